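# Synthetic multi-sample tumor cohort generator. Emits a VCF (GT, DP, AD),
# a sample manifest, and a truth table of planted variant classes so every
# filtering tool can be tested end-to-end without external data.
#
# Planted allele-frequency patterns (per patient; normal at time 0, tumors
# at times 1..T):
#   truncal       normal 0, all tumors share one AF drawn from [0.2, 0.6]
#   bottleneck    normal 0, tumor AF at time t is s*(t-1) with the slope s
#                 drawn from [0.1, 0.3] (so the first tumor is at 0 and the
#                 variant is a pure riser, not also truncal)
#   loh           normal 0.5 (germline heterozygous), all tumors 1.0
#   unique        AF from [0.2, 0.6] only in the first tumor time point of
#                 each patient (the designated target subset), 0 elsewhere
#   germline_flat all samples 0.5
#   noise         either one AF from [0.1, 0.9] uniform across all samples,
#                 or a sub-threshold AF (< 0.05) in a single middle tumor
#                 sample; both fail every default tool predicate
#
# AFs are realized through integer depths: DP ~ Poisson(depth_mean), the
# planted AF is jittered by Normal(0, af_noise_sd), and the alt read count
# is round(AF * DP) so that zero jitter yields exact recovery up to
# rounding. AD is written as "ref,alt" with ref = DP - alt.

SIM_CLASSES <- c("truncal", "bottleneck", "loh", "unique", "germline_flat")

#' Configuration for the synthetic cohort generator
#'
#' @param n_patients Number of patients.
#' @param tumors_per_patient Tumor biopsies per patient (times 1..T); at
#'   least 2 when bottleneck variants are planted.
#' @param n_variants Total variants; those beyond the planted class counts
#'   become noise.
#' @param class_counts Named integer vector with counts for any of
#'   `truncal`, `bottleneck`, `loh`, `unique`, `germline_flat` (and
#'   optionally `noise`; remaining variants are noise regardless).
#' @param depth_mean Expected per-sample read depth (Poisson mean).
#' @param af_noise_sd Standard deviation of per-sample AF jitter added to
#'   the planted AF before read counts are realized.
#' @param purity Tumor purity written to the manifest: a single fraction
#'   applied to every tumor sample, or `NULL` to omit purities.
#' @param ann_pass_frac Fraction of variants whose annotations pass the
#'   canonical cancer filter (impact not LOW, in the CGI gene catalog, and
#'   CIViC level A/B or rating >= 4); the rest fail at least one component.
#' @param seed RNG seed; a fixed seed makes the output byte-identical.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 1L, tumors_per_patient = 3L,
                       n_variants = 300L,
                       class_counts = c(truncal = 20L, bottleneck = 20L,
                                        loh = 20L, unique = 20L,
                                        germline_flat = 20L),
                       depth_mean = 100, af_noise_sd = 0.01,
                       purity = NULL, ann_pass_frac = 0.5, seed = 1L) {
  cc <- stats::setNames(rep(0L, length(SIM_CLASSES)), SIM_CLASSES)
  if (length(class_counts)) {
    extra <- setdiff(names(class_counts), c(SIM_CLASSES, "noise"))
    if (length(extra))
      stop("unknown class(es) in class_counts: ",
           paste(extra, collapse = ", "), call. = FALSE)
    keep <- intersect(names(class_counts), SIM_CLASSES)
    cc[keep] <- as.integer(class_counts[keep])
  }
  n_planted <- sum(cc) + if ("noise" %in% names(class_counts))
    as.integer(class_counts[["noise"]]) else 0L
  if (n_planted > n_variants)
    stop("class counts (", n_planted, ") exceed n_variants (",
         n_variants, ")", call. = FALSE)
  if (cc[["bottleneck"]] > 0L && tumors_per_patient < 2L)
    stop("bottleneck variants need at least 2 tumor time points",
         call. = FALSE)
  stopifnot(n_patients >= 1L, tumors_per_patient >= 1L,
            depth_mean > 0, af_noise_sd >= 0,
            ann_pass_frac >= 0, ann_pass_frac <= 1)
  if (!is.null(purity))
    stopifnot(length(purity) == 1L, purity > 0, purity <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 tumors_per_patient = as.integer(tumors_per_patient),
                 n_variants = as.integer(n_variants),
                 class_counts = cc,
                 depth_mean = depth_mean, af_noise_sd = af_noise_sd,
                 purity = purity, ann_pass_frac = ann_pass_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# planted AF vector for one patient (times 0, 1..T) given a class label
planted_afs <- function(class, n_tumors) {
  t <- seq_len(n_tumors)
  switch(class,
    truncal = c(0, rep(runif(1L, 0.2, 0.6), n_tumors)),
    bottleneck = c(0, runif(1L, 0.1, 0.3) * (t - 1)),
    loh = c(0.5, rep(1, n_tumors)),
    unique = c(0, runif(1L, 0.2, 0.6), rep(0, n_tumors - 1L)),
    germline_flat = rep(0.5, n_tumors + 1L),
    noise = {
      if (n_tumors >= 2L && runif(1L) < 0.5) {
        v <- rep(0, n_tumors + 1L)
        v[[1L + min(2L, n_tumors)]] <- runif(1L, 0.005, 0.04)
        v
      } else rep(runif(1L, 0.1, 0.9), n_tumors + 1L)
    },
    stop("unknown class: ", class))
}

#' Simulate a synthetic tumor cohort
#'
#' Writes `<out_prefix>.vcf`, `<out_prefix>.manifest` and
#' `<out_prefix>.truth.tsv` (planted class label plus planted per-sample
#' AFs, `#`-prefixed header comments record the unique-tool target samples).
#' With a fixed seed the three files are byte-identical across runs.
#'
#' @param config A [sim_config()].
#' @param out_prefix Output path prefix.
#' @return Invisibly, a list with the three file paths, the truth table
#'   data.frame, the `cohort`, and `unique_target` (the sample names planted
#'   unique variants are private to).
#' @export
simulate_cohort <- function(config, out_prefix) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  }
  set.seed(config$seed)

  n_t <- config$tumors_per_patient
  patients <- paste0("p", seq_len(config$n_patients))
  samp <- do.call(rbind, lapply(patients, function(p) {
    data.frame(family_id = p,
               name = c(paste0(p, "_N"), paste0(p, "_T", seq_len(n_t))),
               paternal_id = "0", maternal_id = "0",
               sex = 0L, phenotype = 0L, patient_id = p,
               time = c(0, seq_len(n_t)),
               purity = if (is.null(config$purity)) NA_real_ else
                 c(NA_real_, rep(config$purity, n_t)),
               stringsAsFactors = FALSE)
  }))
  cohort <- new_cohort(samp)
  n_s <- nrow(samp)
  unique_target <- paste0(patients, "_T1")

  n <- config$n_variants
  cc <- config$class_counts
  labels <- c(rep(names(cc), cc), rep("noise", n - sum(cc)))
  labels <- sample(labels)

  # variant coordinates: contiguous chromosome blocks, increasing positions
  n_chrom <- min(5L, n)
  chrom_idx <- rep(seq_len(n_chrom), each = ceiling(n / n_chrom))[seq_len(n)]
  chrom <- paste0("chr", chrom_idx)
  local_i <- stats::ave(seq_len(n), chrom_idx, FUN = seq_along)
  pos <- 1000L + 137L * local_i                # 1-based VCF POS
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")

  # planted AFs per sample (per patient, same class, independent draws)
  af_plant <- matrix(0, n, n_s, dimnames = list(NULL, samp$name))
  for (i in seq_len(n))
    for (p in patients) {
      cols <- which(samp$patient_id == p)
      af_plant[i, cols] <- planted_afs(labels[[i]], n_t)
    }

  # realized depths and alt reads
  dp <- matrix(pmax(1L, stats::rpois(n * n_s, config$depth_mean)), n, n_s)
  af_real <- af_plant
  if (config$af_noise_sd > 0)
    af_real <- af_real + stats::rnorm(n * n_s, 0, config$af_noise_sd)
  af_real <- pmin(pmax(af_real, 0), 1)
  ad_alt <- matrix(as.integer(round(af_real * dp)), n, n_s)
  ad_ref <- dp - ad_alt
  obs_af <- ad_alt / dp
  gt <- matrix("0/1", n, n_s)
  gt[ad_alt == 0L] <- "0/0"
  gt[obs_af >= 0.9] <- "1/1"

  # annotations: a fraction passes the canonical cancer filter
  gene <- paste0("GENE", seq_len(n))
  pass_ann <- runif(n) < config$ann_pass_frac
  impact <- ifelse(runif(n) < 0.5, "HIGH", "MED")
  cgi <- gene
  civic_level <- ifelse(runif(n) < 0.5, "A", "B")
  civic_rating <- round(runif(n, 4, 5), 2)
  fail_mode <- sample(1:3, n, replace = TRUE)
  impact[!pass_ann & fail_mode == 1L] <- "LOW"
  cgi[!pass_ann & fail_mode == 2L] <- NA_character_
  low_idx <- !pass_ann & fail_mode == 3L
  civic_level[low_idx] <- "C"
  civic_rating[low_idx] <- round(runif(sum(low_idx), 0, 3.9), 2)

  ## write VCF
  vcf_path <- paste0(out_prefix, ".vcf")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=tumorgem-simulate",
    "##INFO=<ID=gene,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=impact_severity,Number=1,Type=String,Description=\"Predicted impact severity\">",
    "##INFO=<ID=cgi_gene,Number=1,Type=String,Description=\"CGI cancer gene catalog entry\">",
    "##INFO=<ID=civic_gene_max_level,Number=1,Type=String,Description=\"Max CIViC evidence level for the gene\">",
    "##INFO=<ID=civic_gene_max_rating,Number=1,Type=Float,Description=\"Max CIViC rating for the gene\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste0("##contig=<ID=chr", seq_len(n_chrom), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samp$name), collapse = "\t"))
  info <- vapply(seq_len(n), function(i) {
    f <- c(paste0("gene=", gene[[i]]),
           paste0("impact_severity=", impact[[i]]),
           if (!is.na(cgi[[i]])) paste0("cgi_gene=", cgi[[i]]),
           paste0("civic_gene_max_level=", civic_level[[i]]),
           paste0("civic_gene_max_rating=",
                  sprintf("%.2f", civic_rating[[i]])))
    paste(f, collapse = ";")
  }, "")
  geno_fields <- vapply(seq_len(n), function(i)
    paste(sprintf("%s:%d:%d,%d", gt[i, ], dp[i, ], ad_ref[i, ],
                  ad_alt[i, ]), collapse = "\t"), "")
  body <- paste(chrom, pos, ".", ref, alt, "50", "PASS", info, "GT:DP:AD",
                geno_fields, sep = "\t")
  writeLines(c(hdr, body), vcf_path)

  ## write manifest
  manifest_path <- paste0(out_prefix, ".manifest")
  write_manifest(cohort, manifest_path)

  ## write truth table
  truth_path <- paste0(out_prefix, ".truth.tsv")
  truth <- data.frame(chrom = chrom, start = pos - 1L,
                      end = pos - 1L + nchar(ref), ref = ref, alt = alt,
                      class = labels, stringsAsFactors = FALSE)
  af_cols <- as.data.frame(af_plant)
  names(af_cols) <- paste0("af_", samp$name)
  truth <- cbind(truth, af_cols)
  con <- file(truth_path, "w")
  writeLines(paste0("#unique_target=",
                    paste(unique_target, collapse = ",")), con)
  writeLines(paste(names(truth), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(truth, function(x)
    if (is.numeric(x)) sprintf("%.6g", x) else x), list(sep = "\t"))), con)
  close(con)

  invisible(list(vcf = vcf_path, manifest = manifest_path,
                 truth = truth_path, truth_table = truth,
                 cohort = cohort, unique_target = unique_target,
                 config = config))
}

#' Read a simulation configuration from a key-value file
#'
#' The file is YAML: top-level keys match the [sim_config()] arguments, with
#' `class_counts` given as a nested mapping.
#'
#' @param path Path to the configuration file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown simulation config key(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  if (!is.null(raw$class_counts))
    raw$class_counts <- unlist(raw$class_counts)
  do.call(sim_config, raw)
}
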