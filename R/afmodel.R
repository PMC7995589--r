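# Allele-frequency model: sample selection, purity correction, depth gating,
# and assembly of per-variant AF/depth matrices for the filtering tools.

#' Select the samples a tool will consider
#'
#' Returns the explicit `include` list when given, otherwise all cohort
#' samples. Explicit lists are reordered to manifest (= stored VCF) order so
#' that AF vectors stay paired with sorted time values; slope computation
#' relies on time-consistent pairing, not on list position.
#'
#' @param cohort A `cohort`.
#' @param include Optional character vector of sample names.
#' @return Character vector of sample names in manifest order.
#' @export
select_samples <- function(cohort, include = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  all_names <- cohort$samples$name
  if (is.null(include) || length(include) == 0L) return(all_names)
  unknown <- setdiff(include, all_names)
  if (length(unknown))
    stop("unknown sample name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  all_names[all_names %in% include]
}

#' Purity-correct an allele frequency
#'
#' Divides the observed alt-allele fraction by the tumor cell fraction
#' (purity) of the biopsy and clamps the result to 1; an impure biopsy
#' dilutes somatic variant allele frequencies by admixed normal cells, and
#' division by cellularity is the standard correction. The missing-value
#' sentinel -1 passes through unchanged.
#'
#' @param af Numeric vector of allele fractions in \[0, 1\], or -1.
#' @param purity Numeric vector of purities in (0, 1] (recycled).
#' @return Corrected frequencies, clamped to \[0, 1\]; -1 preserved.
#' @examples
#' purity_adjust(0.1, 0.5)  # 0.2
#' purity_adjust(0.9, 0.5)  # 1 (clamped)
#' @export
purity_adjust <- function(af, purity) {
  stopifnot(all(purity > 0 & purity <= 1))
  adj <- pmin(af / rep_len(purity, length(af)), 1)
  ifelse(af < 0, af, adj)
}

#' Minimum-depth gate across samples
#'
#' TRUE iff every considered sample has read depth at least `minDP`. A
#' missing depth (-1) fails the gate whenever `minDP > 0`; at `minDP = 0`
#' the gate is disabled and always passes.
#'
#' @param depths Integer vector of per-sample depths (-1 = missing).
#' @param minDP Minimum required depth (>= 0).
#' @return Logical scalar.
#' @export
depth_gate <- function(depths, minDP) {
  stopifnot(length(minDP) == 1L, minDP >= 0)
  if (minDP == 0) return(TRUE)
  all(depths >= minDP)
}

#' Assemble the allele-frequency matrix for selected samples
#'
#' Builds variant-by-sample matrices of alt-allele frequencies, depths and
#' genotype classes restricted to the selected samples, with optional purity
#' correction. Samples lacking a manifest purity value are treated as purity
#' 1.0 when correction is requested, with a warning naming them.
#'
#' @param db Database path or connection.
#' @param samples Optional explicit sample list (see [select_samples()]).
#' @param purity Apply purity correction to the frequencies?
#' @param variant_ids Optional restriction to specific variants.
#' @return A list with `variant_id`, `samples`, `times` (per selected
#'   sample), `patient_id` (per selected sample), and matrices `afs`,
#'   `depths`, `gt_types`.
#' @export
af_matrix <- function(db, samples = NULL, purity = FALSE,
                      variant_ids = NULL) {
  h <- db_connect(db)
  if (h$own) on.exit(DBI::dbDisconnect(h$con), add = TRUE)
  cohort <- db_cohort(h$con)
  sel <- select_samples(cohort, samples)
  g <- fetch_genotypes(h$con, variant_ids)

  afs <- g$gt_alt_freqs[, sel, drop = FALSE]
  if (isTRUE(purity)) {
    pur <- cohort$samples$purity[match(sel, cohort$samples$name)]
    if (anyNA(pur)) {
      warning("no purity recorded for sample(s) ",
              paste(sel[is.na(pur)], collapse = ", "),
              "; treating their purity as 1.0", call. = FALSE)
      pur[is.na(pur)] <- 1
    }
    for (j in seq_along(sel)) afs[, j] <- purity_adjust(afs[, j], pur[[j]])
  }
  idx <- match(sel, cohort$samples$name)
  list(variant_id = g$variant_id,
       samples = sel,
       times = cohort$samples$time[idx],
       patient_id = cohort$samples$patient_id[idx],
       afs = afs,
       depths = g$gt_depths[, sel, drop = FALSE],
       gt_types = g$gt_types[, sel, drop = FALSE])
}
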