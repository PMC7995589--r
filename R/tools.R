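# Allele-frequency-pattern filtering tools: bottleneck, loh, truncal,
# unique, set_somatic. Each tool evaluates a per-variant predicate over the
# AF matrix of the considered samples, patient by patient, and returns the
# union of per-patient hits tagged with patient_id. All tools share the
# depth gate, the optional somatic gate, and optional annotation filtering
# pushed into the database scan.

#' Shared tool parameters
#'
#' Bundles the thresholds and sample-selection options shared by the
#' filtering tools. Boundary semantics: the bottleneck slope must strictly
#' exceed `minSlope`; truncal tumor AFs must be strictly greater than
#' `maxNorm`; unique-tool AFs must strictly exceed `minAF` in the specific
#' samples while other samples stay at or below `maxOthers`.
#'
#' @param minDP Minimum read depth required in every considered sample
#'   (0 disables the gate).
#' @param maxNorm Maximum allele frequency allowed in normal samples
#'   (bottleneck, truncal). Default 0.
#' @param minSlope Bottleneck slope threshold. Default 0.05.
#' @param minAF Unique tool: minimum AF that must be exceeded in the
#'   specified samples. Default 0.
#' @param maxOthers Unique tool: maximum AF allowed in all other considered
#'   samples. Default 0.
#' @param hetLo,hetHi Heterozygosity band for the normal sample in the loh
#'   tool. Defaults 0.3 and 0.7.
#' @param lohTumorDelta loh tool: maximum distance of a tumor AF from 0 or
#'   from 1 to call the site homozygous. Default 0.05.
#' @param specific Character vector of sample names for the unique tool.
#' @param samples Optional explicit list of considered samples.
#' @param purity Purity-correct allele frequencies?
#' @param somatic_only Restrict evaluation to variants flagged somatic?
#' @return A `tool_params` list.
#' @export
tool_params <- function(minDP = 0L, maxNorm = 0, minSlope = 0.05,
                        minAF = 0, maxOthers = 0, hetLo = 0.3, hetHi = 0.7,
                        lohTumorDelta = 0.05, specific = NULL,
                        samples = NULL, purity = FALSE,
                        somatic_only = FALSE) {
  stopifnot(minDP >= 0,
            maxNorm >= 0, maxNorm <= 1,
            minAF >= 0, minAF <= 1,
            maxOthers >= 0, maxOthers <= 1,
            hetLo < hetHi, lohTumorDelta >= 0)
  structure(list(minDP = as.integer(minDP), maxNorm = maxNorm,
                 minSlope = minSlope, minAF = minAF, maxOthers = maxOthers,
                 hetLo = hetLo, hetHi = hetHi,
                 lohTumorDelta = lohTumorDelta, specific = specific,
                 samples = samples, purity = isTRUE(purity),
                 somatic_only = isTRUE(somatic_only)),
            class = "tool_params")
}

#' Least-squares slope of allele frequency over time
#'
#' Ordinary least-squares slope of the allele frequencies regressed on the
#' sampling times: `sum((t - mean(t)) * (a - mean(a))) / sum((t - mean(t))^2)`.
#'
#' @param times Numeric vector of sampling times (>= 2 values, not all
#'   equal).
#' @param afs Numeric vector of allele frequencies, same length.
#' @return The slope (change in allele frequency per unit time).
#' @examples
#' af_slope(c(1, 2, 3), c(0, 0.1, 0.3))  # 0.15
#' @export
af_slope <- function(times, afs) {
  stopifnot(length(times) == length(afs), length(times) >= 2L)
  tc <- times - mean(times)
  ss <- sum(tc^2)
  if (ss == 0) stop("times must not all be equal", call. = FALSE)
  sum(tc * (afs - mean(afs))) / ss
}

#' Somatic gate
#'
#' TRUE when `somatic_only` is off, otherwise the variant's `is_somatic`
#' flag.
#'
#' @param is_somatic Logical/integer vector of somatic flags.
#' @param somatic_only Is the restriction requested?
#' @return Logical vector.
#' @export
somatic_gate <- function(is_somatic, somatic_only) {
  if (!isTRUE(somatic_only)) return(rep(TRUE, length(is_somatic)))
  as.logical(is_somatic)
}

# numeric-aware contig ordering: chr1 < chr2 < ... < chr10 < chrX < chrY
chrom_rank <- function(chrom) {
  base <- sub("^[Cc][Hh][Rr]", "", chrom)
  num <- suppressWarnings(as.numeric(base))
  special <- c(X = 1e6, Y = 1e6 + 1, M = 1e6 + 2, MT = 1e6 + 2)
  num[is.na(num)] <- special[toupper(base[is.na(num)])]
  num[is.na(num)] <- 2e6
  num
}

check_somatic_ready <- function(con, somatic_only) {
  if (!isTRUE(somatic_only)) return(invisible(NULL))
  set_ran <- identical(db_meta_get(con, "somatic_set"), "1")
  avail <- identical(db_meta_get(con, "somatic_available"), "1")
  if (!set_ran && !avail)
    stop("--somatic-only requested but no somatic flags exist; ",
         "run set_somatic first (or load a VCF with a somatic INFO flag)",
         call. = FALSE)
  invisible(NULL)
}

# Shared tool driver. `predicate` receives, per patient, the AF and depth
# sub-matrices of the candidate variants restricted to that patient's
# considered samples (plus their times and names) and returns a list with
# `pass` (logical vector over candidate variants) and optionally `stat`
# (numeric vector, e.g. the bottleneck slope).
run_tool <- function(db, params, tool, predicate, needs_tumor = FALSE,
                     columns = NULL, filter = NULL) {
  stopifnot(inherits(params, "tool_params"))
  h <- db_connect(db)
  if (h$own) on.exit(DBI::dbDisconnect(h$con), add = TRUE)
  con <- h$con

  check_somatic_ready(con, params$somatic_only)
  if (is.null(columns))
    columns <- c("chrom", "start", "end", "ref", "alt", "gene")
  rows <- fetch_variants(con, columns = unique(c(columns, "is_somatic")),
                         where = filter)
  rows <- rows[somatic_gate(rows$is_somatic, params$somatic_only), ,
               drop = FALSE]
  n_candidates <- nrow(rows)
  am <- af_matrix(con, samples = params$samples, purity = params$purity,
                  variant_ids = rows$variant_id)

  cohort <- db_cohort(con)
  if (isTRUE(needs_tumor) && length(tumors(cohort)) == 0L)
    stop(tool, " requires at least one tumor sample in the cohort",
         call. = FALSE)

  hits <- list()
  n_missing_af <- 0L
  for (p in names(cohort$by_patient)) {
    pidx <- which(am$patient_id == p)
    if (length(pidx) == 0L) next
    res <- predicate(afs = am$afs[, pidx, drop = FALSE],
                     depths = am$depths[, pidx, drop = FALSE],
                     times = am$times[pidx],
                     samples = am$samples[pidx],
                     patient = p)
    if (is.null(res)) next
    pass <- res$pass
    # a missing AF in any considered sample disqualifies the variant
    miss <- rowSums(am$afs[, pidx, drop = FALSE] < 0) > 0L
    n_missing_af <- n_missing_af + sum(miss & pass, na.rm = TRUE)
    pass <- pass & !miss
    if (params$minDP > 0L)
      pass <- pass & rowSums(am$depths[, pidx, drop = FALSE] <
                               params$minDP) == 0L
    pass[is.na(pass)] <- FALSE
    if (!any(pass)) next
    hit <- data.frame(variant_id = am$variant_id[pass],
                      patient_id = p, stringsAsFactors = FALSE)
    if (!is.null(res$stat)) hit$stat <- res$stat[pass]
    hits[[p]] <- hit
  }

  hit <- if (length(hits)) do.call(rbind, hits) else
    data.frame(variant_id = integer(0), patient_id = character(0),
               stringsAsFactors = FALSE)
  out <- merge(hit, rows, by = "variant_id", sort = FALSE)
  if ("stat" %in% names(out))
    names(out)[names(out) == "stat"] <- "slope"
  keep <- unique(c("variant_id", "patient_id", columns,
                   intersect("slope", names(out))))
  # per-sample AFs used in the decision
  afdf <- as.data.frame(am$afs[match(out$variant_id, am$variant_id), ,
                               drop = FALSE])
  if (ncol(afdf)) names(afdf) <- paste0("af_", am$samples)
  out <- cbind(out[, keep, drop = FALSE], afdf)
  if (nrow(out)) {
    out <- out[order(chrom_rank(out$chrom), out$chrom, out$start,
                     out$variant_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (n_missing_af > 0L)
    message(n_missing_af,
            " variant-patient evaluation(s) excluded for missing AFs")
  message(sprintf("%s: %d candidate variant(s), %d returned", tool,
                  n_candidates, length(unique(out$variant_id))))
  out
}

#' Variants with rising allele frequency across tumor time points
#'
#' For each patient, regresses the tumor-sample allele frequencies on their
#' manifest time values and returns variants whose slope strictly exceeds
#' `minSlope` (default 0.05). Normal (time 0) samples never enter the
#' regression; when they are among the considered samples they act only as a
#' germline gate: every normal AF must be at or below `maxNorm` (default 0).
#' Patients with fewer than two considered tumor time points are skipped
#' with a one-time warning.
#'
#' @param db Database path or connection.
#' @param params A [tool_params()] object.
#' @param columns Output columns (default chrom, start, end, ref, alt,
#'   gene).
#' @param filter Optional annotation filter (SQL WHERE fragment).
#' @return A data.frame of passing variants with `patient_id`, the requested
#'   columns, the fitted `slope`, and the per-sample AFs used.
#' @export
bottleneck <- function(db, params = tool_params(), columns = NULL,
                       filter = NULL) {
  warned <- FALSE
  run_tool(db, params, "bottleneck", needs_tumor = TRUE,
           columns = columns, filter = filter,
           predicate = function(afs, depths, times, samples, patient) {
    tum <- which(times > 0)
    if (length(tum) < 2L || length(unique(times[tum])) < 2L) {
      if (!warned) {
        warning("bottleneck needs >= 2 tumor time points; skipping ",
                "patient(s) without them (first: ", patient, ")",
                call. = FALSE)
        warned <<- TRUE
      }
      return(NULL)
    }
    t <- times[tum]
    tc <- t - mean(t)
    slopes <- as.vector(afs[, tum, drop = FALSE] %*% tc) / sum(tc^2)
    pass <- slopes > params$minSlope
    norm <- which(times == 0)
    if (length(norm) > 0L)
      pass <- pass & rowSums(afs[, norm, drop = FALSE] >
                               params$maxNorm) == 0L
    list(pass = pass, stat = slopes)
  })
}

#' Loss-of-heterozygosity variants
#'
#' Returns variants heterozygous in every considered normal sample (AF
#' within `[hetLo, hetHi]`, defaults 0.3–0.7) whose allele frequency in
#' every considered tumor sample has collapsed to within `lohTumorDelta`
#' (default 0.05) of 0 or of 1. Requires at least one considered normal
#' sample per evaluated patient.
#'
#' @inheritParams bottleneck
#' @return A data.frame of passing variants (see [bottleneck()]).
#' @export
loh <- function(db, params = tool_params(), columns = NULL, filter = NULL) {
  run_tool(db, params, "loh", columns = columns, filter = filter,
           predicate = function(afs, depths, times, samples, patient) {
    norm <- which(times == 0)
    tum <- which(times > 0)
    if (length(norm) == 0L)
      stop("loh requires a normal (time 0) sample among the considered ",
           "samples (patient ", patient, " has none)", call. = FALSE)
    nm <- afs[, norm, drop = FALSE]
    het <- rowSums(nm < params$hetLo | nm > params$hetHi) == 0L
    tm <- afs[, tum, drop = FALSE]
    lost <- rowSums(pmin(abs(tm), abs(1 - tm)) >
                      params$lohTumorDelta) == 0L
    if (length(tum) == 0L) lost <- rep(FALSE, nrow(afs))
    list(pass = het & lost)
  })
}

#' Truncal (clonal) variants
#'
#' Returns variants present in every considered tumor sample but absent from
#' the normals: every considered normal AF at or below `maxNorm` (default 0)
#' and every considered tumor AF strictly greater than `maxNorm`. Requires
#' at least one considered normal sample per evaluated patient.
#'
#' @inheritParams bottleneck
#' @return A data.frame of passing variants (see [bottleneck()]).
#' @export
truncal <- function(db, params = tool_params(), columns = NULL,
                    filter = NULL) {
  run_tool(db, params, "truncal", columns = columns, filter = filter,
           predicate = function(afs, depths, times, samples, patient) {
    norm <- which(times == 0)
    tum <- which(times > 0)
    if (length(norm) == 0L)
      stop("truncal requires a normal (time 0) sample among the ",
           "considered samples (patient ", patient, " has none)",
           call. = FALSE)
    nm <- afs[, norm, drop = FALSE]
    tm <- afs[, tum, drop = FALSE]
    pass <- rowSums(nm > params$maxNorm) == 0L &
      rowSums(tm <= params$maxNorm) == 0L
    if (length(tum) == 0L) pass <- rep(FALSE, nrow(afs))
    list(pass = pass)
  })
}

#' Variants private to a specified sample group
#'
#' Returns variants whose allele frequency strictly exceeds `minAF`
#' (default 0) in every sample listed in `params$specific` while staying at
#' or below `maxOthers` (default 0) in every other considered sample.
#' Patients containing none of the specific samples are skipped.
#'
#' @inheritParams bottleneck
#' @return A data.frame of passing variants (see [bottleneck()]).
#' @export
unique_tool <- function(db, params = tool_params(), columns = NULL,
                        filter = NULL) {
  if (is.null(params$specific) || length(params$specific) == 0L)
    stop("unique requires a non-empty list of specific samples",
         call. = FALSE)
  ch <- db_cohort(db)
  unknown <- setdiff(params$specific, ch$samples$name)
  if (length(unknown))
    stop("unknown sample name(s) in specific list: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  run_tool(db, params, "unique", columns = columns, filter = filter,
           predicate = function(afs, depths, times, samples, patient) {
    sp <- which(samples %in% params$specific)
    if (length(sp) == 0L) return(NULL)
    ot <- setdiff(seq_along(samples), sp)
    inside <- rowSums(afs[, sp, drop = FALSE] <= params$minAF) == 0L
    outside <- rowSums(afs[, ot, drop = FALSE] > params$maxOthers) == 0L
    if (length(ot) == 0L) outside <- rep(TRUE, nrow(afs))
    list(pass = inside & outside)
  })
}

#' Flag somatic variants in the database
#'
#' Writes an `is_somatic` flag for every variant that looks somatic under a
#' simple depth/frequency rule, evaluated per patient: all of the patient's
#' samples have depth at least `minDP`, every normal (time 0) sample has AF
#' at or below `normAF`, and at least one tumor sample has AF at or above
#' `tumorAF`. On a multi-patient database a variant is flagged when the rule
#' holds within at least one patient. The flags are persisted in the
#' `variants` table (rerunning overwrites previous flags) and unlock the
#' `somatic_only` restriction of the filtering tools.
#'
#' @param db Database path or connection.
#' @param minDP Minimum read depth required in all samples (0 disables).
#' @param normAF Maximum allele frequency allowed in normal samples.
#' @param tumorAF Minimum allele frequency required in at least one tumor
#'   sample.
#' @param purity Use purity-corrected allele frequencies?
#' @return The number of variants flagged, invisibly.
#' @export
set_somatic <- function(db, minDP = 0L, normAF = 0, tumorAF = 0,
                        purity = FALSE) {
  h <- db_connect(db)
  if (h$own) on.exit(DBI::dbDisconnect(h$con), add = TRUE)
  con <- h$con
  cohort <- db_cohort(con)
  if (length(normals(cohort)) == 0L)
    stop("set_somatic requires at least one normal (time 0) sample",
         call. = FALSE)
  if (length(tumors(cohort)) == 0L)
    stop("set_somatic requires at least one tumor (time > 0) sample",
         call. = FALSE)

  am <- af_matrix(con, purity = purity)
  flagged <- rep(FALSE, length(am$variant_id))
  for (p in names(cohort$by_patient)) {
    pidx <- which(am$patient_id == p)
    norm <- pidx[am$times[pidx] == 0]
    tum <- pidx[am$times[pidx] > 0]
    if (length(norm) == 0L || length(tum) == 0L) next
    ok <- rep(TRUE, length(am$variant_id))
    if (minDP > 0L)
      ok <- ok & rowSums(am$depths[, pidx, drop = FALSE] < minDP) == 0L
    nm <- am$afs[, norm, drop = FALSE]
    tm <- am$afs[, tum, drop = FALSE]
    ok <- ok & rowSums(nm < 0 | nm > normAF) == 0L
    ok <- ok & rowSums(tm >= 0 & tm >= tumorAF) > 0L
    flagged <- flagged | ok
  }

  if (identical(db_meta_get(con, "somatic_set"), "1"))
    message("set_somatic: overwriting previously set somatic flags")
  DBI::dbExecute(con, "UPDATE variants SET is_somatic = 0")
  ids <- am$variant_id[flagged]
  if (length(ids))
    DBI::dbExecute(con, paste0(
      "UPDATE variants SET is_somatic = 1 WHERE variant_id IN (",
      paste(ids, collapse = ","), ")"))
  db_meta_set(con, "somatic_set", 1L)
  message(sprintf("set_somatic: flagged %d of %d variant(s)",
                  length(ids), length(flagged)))
  invisible(length(ids))
}
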