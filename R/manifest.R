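# Tumor sample manifest: a pedigree-style table extended with patient_id,
# sampling time and optional tumor purity. The manifest defines which VCF
# samples belong to which patient and the temporal order of biopsies.

MANIFEST_COLUMNS <- c("family_id", "name", "paternal_id", "maternal_id",
                      "sex", "phenotype", "patient_id", "time", "purity")
MANIFEST_REQUIRED <- c("name", "patient_id", "time")

#' Parse a tumor sample manifest
#'
#' Reads a pedigree-style sample manifest describing the relationship between
#' sequenced samples: which patient each sample came from (`patient_id`), when
#' it was taken (`time`; 0 marks normal/germline tissue, values greater than 0
#' mark tumor biopsies in sampling order), and optionally the tumor purity
#' (cellularity) of the biopsy as a fraction in (0, 1].
#'
#' The file is tab- or whitespace-delimited; the first non-comment line is the
#' header and must name at least `name`, `patient_id` and `time`. Lines
#' starting with `#` are comments. The classic pedigree columns (`family_id`,
#' `paternal_id`, `maternal_id`, `sex`, `phenotype`) are parsed when present
#' but ignored by all downstream tools. A missing `purity` column, or `.`/`NA`
#' entries in it, are recorded as absent rather than as 1.0 so that purity
#' correction can warn about samples it has to default.
#'
#' @param path Path to the manifest file.
#' @return A `cohort` object: a list with `samples` (a data.frame with one row
#'   per sample, in file order) and `by_patient` (a list mapping each
#'   patient_id to its sample names ordered by time, ties broken by file
#'   order).
#' @examples
#' mf <- tempfile()
#' writeLines(c("family_id\tname\tpaternal_id\tmaternal_id\tsex\tphenotype\tpatient_id\ttime",
#'              "p1\tN1\t0\t0\t0\t0\tp1\t0",
#'              "p1\tT1\t0\t0\t0\t0\tp1\t1"), mf)
#' ch <- parse_manifest(mf)
#' normals(ch)
#' @export
parse_manifest <- function(path) {
  if (!file.exists(path))
    stop("manifest file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 1L)
    stop("manifest is empty: ", path, call. = FALSE)

  # tab-delimited if the header contains a tab, else any whitespace run
  split_fields <- if (grepl("\t", lines[[1L]])) {
    function(x) strsplit(x, "\t", fixed = TRUE)[[1L]]
  } else {
    function(x) strsplit(trimws(x), "\\s+")[[1L]]
  }
  header <- trimws(split_fields(lines[[1L]]))
  missing_cols <- setdiff(MANIFEST_REQUIRED, header)
  if (length(missing_cols))
    stop("manifest header is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  body <- lines[-1L]
  if (length(body) == 0L)
    stop("manifest contains a header but no samples", call. = FALSE)

  rows <- lapply(body, function(ln) {
    f <- trimws(split_fields(ln))
    if (length(f) < length(header))
      f <- c(f, rep(NA_character_, length(header) - length(f)))
    f[seq_along(header)]
  })
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- header

  get_col <- function(col, default) {
    if (col %in% names(tab)) tab[[col]] else rep(default, nrow(tab))
  }
  samples <- data.frame(
    family_id   = get_col("family_id", "0"),
    name        = tab[["name"]],
    paternal_id = get_col("paternal_id", "0"),
    maternal_id = get_col("maternal_id", "0"),
    sex         = suppressWarnings(as.integer(get_col("sex", "0"))),
    phenotype   = suppressWarnings(as.integer(get_col("phenotype", "0"))),
    patient_id  = tab[["patient_id"]],
    time        = suppressWarnings(as.numeric(tab[["time"]])),
    purity      = NA_real_,
    stringsAsFactors = FALSE
  )
  if ("purity" %in% names(tab)) {
    raw <- tab[["purity"]]
    absent <- is.na(raw) | raw %in% c("", ".", "NA", "na", "-")
    val <- suppressWarnings(as.numeric(raw))
    if (any(!absent & is.na(val)))
      stop("non-numeric purity value(s): ",
           paste(unique(raw[!absent & is.na(val)]), collapse = ", "),
           call. = FALSE)
    samples$purity <- ifelse(absent, NA_real_, val)
  }

  dup <- samples$name[duplicated(samples$name)]
  if (length(dup))
    stop("duplicate sample name(s) in manifest: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (any(is.na(samples$time)))
    stop("non-numeric or missing time value for sample(s): ",
         paste(samples$name[is.na(samples$time)], collapse = ", "),
         call. = FALSE)
  if (any(samples$time < 0))
    stop("negative time value for sample(s): ",
         paste(samples$name[samples$time < 0], collapse = ", "),
         call. = FALSE)
  bad_pur <- !is.na(samples$purity) &
    (samples$purity <= 0 | samples$purity > 1)
  if (any(bad_pur))
    stop("purity outside (0, 1] for sample(s): ",
         paste(samples$name[bad_pur], collapse = ", "), call. = FALSE)

  new_cohort(samples)
}

new_cohort <- function(samples) {
  rownames(samples) <- NULL
  by_patient <- lapply(split(seq_len(nrow(samples)), samples$patient_id),
                       function(idx) {
                         # order by time; ties keep file order
                         idx <- idx[order(samples$time[idx])]
                         samples$name[idx]
                       })
  structure(list(samples = samples, by_patient = by_patient),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n_norm <- sum(x$samples$time == 0)
  cat(sprintf("cohort: %d samples, %d patient(s), %d normal / %d tumor\n",
              nrow(x$samples), length(x$by_patient), n_norm,
              nrow(x$samples) - n_norm))
  print(x$samples, ...)
  invisible(x)
}

check_patient <- function(cohort, patient) {
  if (identical(patient, "all")) return(invisible(NULL))
  unknown <- setdiff(patient, cohort$samples$patient_id)
  if (length(unknown))
    stop("unknown patient_id: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  invisible(NULL)
}

#' Normal (germline) samples of a cohort
#'
#' Samples with `time == 0`, i.e. normal/germline tissue, optionally
#' restricted to one patient. May be empty; tools that require a normal
#' sample raise their own error in that case.
#'
#' @param cohort A `cohort` from [parse_manifest()].
#' @param patient A patient_id, or `"all"` (default) for every patient.
#' @return Character vector of sample names in manifest order.
#' @export
normals <- function(cohort, patient = "all") {
  stopifnot(inherits(cohort, "cohort"))
  check_patient(cohort, patient)
  s <- cohort$samples
  keep <- s$time == 0
  if (!identical(patient, "all")) keep <- keep & s$patient_id %in% patient
  s$name[keep]
}

#' Tumor samples of a cohort
#'
#' Samples with `time > 0`, optionally restricted to one patient.
#'
#' @inheritParams normals
#' @return Character vector of sample names in manifest order.
#' @export
tumors <- function(cohort, patient = "all") {
  stopifnot(inherits(cohort, "cohort"))
  check_patient(cohort, patient)
  s <- cohort$samples
  keep <- s$time > 0
  if (!identical(patient, "all")) keep <- keep & s$patient_id %in% patient
  s$name[keep]
}

#' Write a cohort back to manifest text
#'
#' Inverse of [parse_manifest()]: re-parsing the written file yields an
#' identical cohort. Absent purity is written as `.`.
#'
#' @param cohort A `cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  s <- cohort$samples
  pur <- ifelse(is.na(s$purity), ".", format(s$purity, trim = TRUE))
  tim <- format(s$time, trim = TRUE, scientific = FALSE)
  lines <- c(paste(MANIFEST_COLUMNS, collapse = "\t"),
             paste(s$family_id, s$name, s$paternal_id, s$maternal_id,
                   s$sex, s$phenotype, s$patient_id, tim, pur, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
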