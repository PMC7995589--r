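# VCF -> relational database loader and readers.
#
# The database is a single SQLite file with three tables:
#   variants : one row per decomposed (single-ALT) VCF record; core columns
#              variant_id, chrom, start (0-based), end (half-open), ref, alt,
#              gene, is_somatic, plus one typed column per VCF INFO field
#              (Integer -> INTEGER, Float -> REAL, Flag -> INTEGER 0/1,
#              String -> TEXT) and three BLOB columns holding the per-sample
#              genotype vectors (gzip-compressed serialized vectors).
#   samples  : the manifest contents, reordered to the VCF sample order.
#   meta     : key/value pairs (schema version, load/skip counts, whether
#              somatic flags are available).

CORE_COLUMNS <- c("variant_id", "chrom", "start", "end", "ref", "alt",
                  "gene", "is_somatic")
BLOB_COLUMNS <- c("gt_types", "gt_depths", "gt_alt_freqs")
SCHEMA_VERSION <- "1"

# genotype class codes shared with the GEMINI family of tools
GT_HOM_REF <- 0L
GT_HET     <- 1L
GT_UNKNOWN <- 2L
GT_HOM_ALT <- 3L

## ---- connection helpers -----------------------------------------------

db_connect <- function(db) {
  if (inherits(db, "DBIConnection")) return(list(con = db, own = FALSE))
  if (!is.character(db) || length(db) != 1L)
    stop("db must be a file path or DBI connection", call. = FALSE)
  if (!file.exists(db))
    stop("database file not found: ", db, call. = FALSE)
  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  ver <- tryCatch(db_meta_get(con, "schema_version"), error = function(e) NULL)
  if (is.null(ver) || !identical(ver, SCHEMA_VERSION))
    stop("not a tumorgem database (missing or mismatched schema version): ",
         db, call. = FALSE)
  list(con = con, own = TRUE)
}

db_meta_get <- function(con, key) {
  r <- DBI::dbGetQuery(con, "SELECT value FROM meta WHERE key = :k",
                       params = list(k = key))
  if (nrow(r) == 0L) NULL else r$value[[1L]]
}

db_meta_set <- function(con, key, value) {
  DBI::dbExecute(con,
    "INSERT OR REPLACE INTO meta (key, value) VALUES (:k, :v)",
    params = list(k = key, v = as.character(value)))
  invisible(NULL)
}

blob_encode <- function(x) memCompress(serialize(x, NULL, xdr = TRUE), "gzip")
blob_decode <- function(raw) unserialize(memDecompress(raw, "gzip"))

## ---- INFO column handling ---------------------------------------------

sanitize_column <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  x <- sub("^_+", "", x)
  x <- sub("_+$", "", x)
  ifelse(nzchar(x), x, "x")
}

# resolve collisions with core columns and among sanitized names
resolve_columns <- function(sanitized) {
  out <- sanitized
  for (i in seq_along(out)) {
    nm <- out[[i]]
    if (nm %in% c(CORE_COLUMNS, BLOB_COLUMNS)) nm <- paste0(nm, "_info")
    k <- 2L
    while (nm %in% out[seq_len(i - 1L)]) {
      nm <- paste0(out[[i]], "_", k)
      k <- k + 1L
    }
    out[[i]] <- nm
  }
  out
}

## ---- allele-frequency estimator ---------------------------------------

#' Per-sample alternate-allele frequency
#'
#' Estimates the fraction of reads supporting the alternate allele for one or
#' more sample genotypes. When allelic depths are available and the total
#' depth is positive, the estimate is `alt_depth / total_depth`, clamped to 1
#' (with a warning) if the alternate depth exceeds the total. When allelic
#' depths are absent but a genotype was called, the genotype dosage is used
#' instead (HOM_REF -> 0, HET -> 0.5, HOM_ALT -> 1). Otherwise the sentinel
#' value -1 marks the frequency as uncomputable.
#'
#' @param alt_depth Integer vector of alternate-allele read depths (NA when
#'   missing).
#' @param total_depth Integer vector of total read depths (NA when missing).
#' @param gt_type Integer vector of genotype class codes (0 = HOM_REF,
#'   1 = HET, 2 = UNKNOWN, 3 = HOM_ALT).
#' @return Numeric vector of frequencies in \[0, 1\], or -1 where
#'   uncomputable.
#' @examples
#' alt_allele_frequency(5L, 50L, 1L)    # 0.1
#' alt_allele_frequency(NA, NA, 1L)     # 0.5 (dosage fallback)
#' alt_allele_frequency(0L, 0L, 1L)     # -1
#' @export
alt_allele_frequency <- function(alt_depth, total_depth, gt_type) {
  n <- max(length(alt_depth), length(total_depth), length(gt_type))
  alt_depth <- rep_len(as.numeric(alt_depth), n)
  total_depth <- rep_len(as.numeric(total_depth), n)
  gt_type <- rep_len(as.integer(gt_type), n)

  af <- rep(-1, n)
  use_ad <- !is.na(alt_depth) & !is.na(total_depth) & total_depth > 0
  af[use_ad] <- alt_depth[use_ad] / total_depth[use_ad]
  over <- use_ad & alt_depth > total_depth
  if (any(over)) {
    af[over] <- 1
    warning(sum(over), " genotype(s) with alt depth > total depth; ",
            "allele frequency clamped to 1", call. = FALSE)
  }
  dosage <- c(`0` = 0, `1` = 0.5, `3` = 1)
  no_ad <- is.na(alt_depth) & gt_type %in% c(GT_HOM_REF, GT_HET, GT_HOM_ALT)
  af[no_ad] <- dosage[as.character(gt_type[no_ad])]
  af
}

# genotype string ("0/1", "1|1", "./.", "./1") -> class code
gt_type_from_string <- function(gt) {
  u <- unique(gt)
  code <- vapply(u, function(g) {
    if (is.na(g)) return(GT_UNKNOWN)
    al <- strsplit(g, "[/|]")[[1L]]
    if (length(al) == 0L || any(al == "." | al == "")) return(GT_UNKNOWN)
    if (all(al == "0")) return(GT_HOM_REF)
    if (all(al != "0")) return(GT_HOM_ALT)
    GT_HET
  }, integer(1L))
  unname(code[match(gt, u)])
}

## ---- loader ------------------------------------------------------------

#' Load an annotated VCF and sample manifest into a variant database
#'
#' Creates a single-file SQLite database from a multi-sample VCF (v4.x, plain
#' or bgzipped) and a sample manifest (see [parse_manifest()]). Every
#' single-ALT record becomes one row of the `variants` table; records with
#' more than one ALT allele are skipped with a counted warning (the loader
#' expects a decomposed/normalized VCF). INFO fields declared in the header
#' become typed annotation columns (names lowercased, non-alphanumerics
#' replaced by underscores; collisions with core columns get an `_info`
#' suffix). An INFO field named `gene` populates the core `gene` column; a
#' `Flag` field named `somatic` or `is_somatic` initializes the core
#' `is_somatic` column. Multi-valued INFO fields are stored as their first
#' value with a counted warning.
#'
#' Per-sample genotype class, read depth (FORMAT `DP`, falling back to the
#' sum of `AD`), and alternate-allele frequency (see
#' [alt_allele_frequency()]) are stored per variant as compressed vectors in
#' VCF sample order, restricted to the manifest samples.
#'
#' @param vcf Path to the VCF file.
#' @param manifest Path to the manifest file, or a `cohort` object.
#' @param db Output database path (overwritten if it exists).
#' @return The database path, invisibly. Load/skip counts are reported via
#'   `message()`.
#' @export
load_db <- function(vcf, manifest, db) {
  cohort <- if (inherits(manifest, "cohort")) manifest
            else parse_manifest(manifest)

  v <- suppressWarnings(VariantAnnotation::readVcf(vcf, genome = "unknown"))
  n_total <- length(v)
  if (n_total == 0L) stop("VCF contains no variant records", call. = FALSE)

  vcf_samples <- VariantAnnotation::samples(VariantAnnotation::header(v))
  missing_s <- setdiff(cohort$samples$name, vcf_samples)
  if (length(missing_s))
    stop("manifest sample(s) absent from VCF: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  # manifest samples in VCF column order (the stored order of all vectors)
  sample_order <- vcf_samples[vcf_samples %in% cohort$samples$name]
  samples <- cohort$samples[match(sample_order, cohort$samples$name), ,
                            drop = FALSE]
  rownames(samples) <- NULL

  n_alt <- S4Vectors::elementNROWS(VariantAnnotation::alt(v))
  keep <- n_alt == 1L
  n_skipped <- sum(!keep)
  if (n_skipped > 0L)
    warning(n_skipped, " multiallelic record(s) skipped ",
            "(decompose/normalize the VCF upstream to keep them)",
            call. = FALSE)
  v <- v[keep]
  n_loaded <- length(v)
  if (n_loaded == 0L) stop("no biallelic records to load", call. = FALSE)

  rr <- SummarizedExperiment::rowRanges(v)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)               # 1-based VCF POS
  ref <- as.character(VariantAnnotation::ref(v))
  alt <- as.character(unlist(VariantAnnotation::alt(v)))
  start0 <- pos - 1L                            # 0-based half-open
  end0 <- start0 + nchar(ref)

  ## INFO columns
  hdr <- VariantAnnotation::info(VariantAnnotation::header(v))
  infodat <- VariantAnnotation::info(v)
  n_multival <- 0L
  gene <- rep(NA_character_, n_loaded)
  is_somatic <- rep(0L, n_loaded)
  somatic_available <- FALSE

  ann <- list()
  ann_keys <- rownames(hdr)
  for (key in ann_keys) {
    val <- infodat[[key]]
    if (is.null(val)) next
    typ <- hdr[key, "Type"]
    if (identical(typ, "Flag")) {
      col <- as.integer(isTRUE_vec(val))
    } else {
      if (is(val, "List") || is.list(val)) {
        lens <- S4Vectors::elementNROWS(val)
        n_multival <- n_multival + sum(lens > 1L)
        val <- vapply(as.list(val),
                      function(x) if (length(x) >= 1L) x[[1L]] else NA,
                      vector(mode_for(typ), 1L))
      }
      col <- switch(typ,
                    Integer = suppressWarnings(as.integer(val)),
                    Float   = suppressWarnings(as.numeric(val)),
                    suppressWarnings(as.character(val)))
    }
    san <- sanitize_column(key)
    if (san == "gene") {
      gene <- as.character(col)
    } else if (san %in% c("somatic", "is_somatic") && identical(typ, "Flag")) {
      is_somatic <- col
      somatic_available <- TRUE
    } else {
      ann[[san]] <- col
    }
  }
  if (n_multival > 0L)
    warning(n_multival, " multi-valued INFO value(s) stored as their ",
            "first element", call. = FALSE)
  if (length(ann)) names(ann) <- resolve_columns(names(ann))

  ## genotype vectors, restricted to manifest samples in VCF order
  geno <- VariantAnnotation::geno(v)
  if (!"GT" %in% names(geno))
    stop("VCF FORMAT must include GT", call. = FALSE)
  gtm <- geno$GT[, sample_order, drop = FALSE]
  gt_types <- matrix(gt_type_from_string(as.vector(gtm)),
                     nrow = n_loaded,
                     dimnames = list(NULL, sample_order))

  dpm <- if ("DP" %in% names(geno)) {
    m <- geno$DP[, sample_order, drop = FALSE]
    suppressWarnings(matrix(as.integer(m), nrow = n_loaded))
  } else matrix(NA_integer_, n_loaded, length(sample_order))

  ad_ref <- ad_alt <- matrix(NA_integer_, n_loaded, length(sample_order))
  if ("AD" %in% names(geno)) {
    adm <- geno$AD[, sample_order, drop = FALSE]
    if (is.array(adm) && length(dim(adm)) == 3L) {
      ad_ref[] <- suppressWarnings(as.integer(adm[, , 1L]))
      ad_alt[] <- suppressWarnings(as.integer(adm[, , 2L]))
    } else {
      pick <- function(x, i)
        if (length(x) >= i && !is.na(x[[i]])) as.integer(x[[i]]) else NA_integer_
      ad_ref[] <- vapply(adm, pick, integer(1L), i = 1L)
      ad_alt[] <- vapply(adm, pick, integer(1L), i = 2L)
    }
  }
  ad_sum <- ad_ref + ad_alt
  depth <- ifelse(!is.na(dpm), dpm, ifelse(!is.na(ad_sum), ad_sum, -1L))
  total <- ifelse(!is.na(dpm) & dpm > 0L, dpm, ad_sum)

  n_clamped <- 0L
  af <- withCallingHandlers(
    alt_allele_frequency(as.vector(ad_alt), as.vector(total),
                         as.vector(gt_types)),
    warning = function(w) {
      n_clamped <<- n_clamped + 1L
      invokeRestart("muffleWarning")
    })
  af <- matrix(af, nrow = n_loaded)
  if (n_clamped > 0L)
    warning("alt depth exceeded total depth for some genotypes; ",
            "frequencies clamped to 1", call. = FALSE)

  ## write the database
  if (file.exists(db)) file.remove(db)
  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  on.exit(DBI::dbDisconnect(con), add = TRUE)

  variants <- data.frame(variant_id = seq_len(n_loaded),
                         chrom = chrom, start = start0, end = end0,
                         ref = ref, alt = alt, gene = gene,
                         is_somatic = is_somatic,
                         stringsAsFactors = FALSE)
  for (nm in names(ann)) variants[[nm]] <- ann[[nm]]
  variants$gt_types <- I(lapply(seq_len(n_loaded), function(i)
    blob_encode(unname(gt_types[i, ]))))
  variants$gt_depths <- I(lapply(seq_len(n_loaded), function(i)
    blob_encode(as.integer(depth[i, ]))))
  variants$gt_alt_freqs <- I(lapply(seq_len(n_loaded), function(i)
    blob_encode(unname(af[i, ]))))

  DBI::dbWriteTable(con, "variants", variants)
  DBI::dbWriteTable(con, "samples",
                    cbind(sample_id = seq_len(nrow(samples)), samples))
  DBI::dbExecute(con,
    "CREATE TABLE meta (key TEXT PRIMARY KEY, value TEXT)")
  db_meta_set(con, "schema_version", SCHEMA_VERSION)
  db_meta_set(con, "n_loaded", n_loaded)
  db_meta_set(con, "n_skipped", n_skipped)
  db_meta_set(con, "n_clamped", n_clamped)
  db_meta_set(con, "somatic_available", as.integer(somatic_available))
  db_meta_set(con, "somatic_set", 0L)

  message(sprintf("loaded %d variant(s), skipped %d multiallelic record(s) into %s",
                  n_loaded, n_skipped, db))
  invisible(db)
}

# VariantAnnotation Flag fields arrive as plain logicals
isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

mode_for <- function(type) {
  switch(type, Integer = "integer", Float = "double", "character")
}

## ---- readers -----------------------------------------------------------

#' Columns available in the variants table
#'
#' @param db Database path or connection.
#' @return Character vector of queryable column names (genotype blob columns
#'   excluded).
#' @export
db_columns <- function(db) {
  h <- db_connect(db)
  if (h$own) on.exit(DBI::dbDisconnect(h$con), add = TRUE)
  setdiff(DBI::dbListFields(h$con, "variants"), BLOB_COLUMNS)
}

#' Cohort stored in a variant database
#'
#' Reconstructs the `cohort` recorded at load time; its sample order is the
#' VCF sample order, which is also the order of all stored genotype vectors.
#'
#' @param db Database path or connection.
#' @return A `cohort` object.
#' @export
db_cohort <- function(db) {
  h <- db_connect(db)
  if (h$own) on.exit(DBI::dbDisconnect(h$con), add = TRUE)
  s <- DBI::dbGetQuery(h$con, "SELECT * FROM samples ORDER BY sample_id")
  s$sample_id <- NULL
  new_cohort(s)
}

#' Fetch variant rows
#'
#' Retrieves variant rows (in `variant_id` order) with the requested columns,
#' optionally restricted by a SQL `WHERE` predicate over annotation columns.
#' The predicate is validated against the existing columns before execution,
#' and the emptiness idiom `col != ''` is rewritten to also exclude NULL
#' (un-annotated) values.
#'
#' @param db Database path or connection.
#' @param columns Character vector of columns to return; default
#'   `chrom, start, end, ref, alt, gene`. `variant_id` is always included.
#' @param where Optional filter expression (SQL WHERE fragment), e.g.
#'   `"impact_severity != 'LOW' and cgi_gene != ''"`.
#' @return A data.frame.
#' @export
fetch_variants <- function(db, columns = NULL, where = NULL) {
  h <- db_connect(db)
  if (h$own) on.exit(DBI::dbDisconnect(h$con), add = TRUE)
  avail <- setdiff(DBI::dbListFields(h$con, "variants"), BLOB_COLUMNS)
  if (is.null(columns))
    columns <- c("chrom", "start", "end", "ref", "alt", "gene")
  bad <- setdiff(columns, avail)
  if (length(bad))
    stop("unknown column(s): ", paste(bad, collapse = ", "),
         "; available columns: ", paste(avail, collapse = ", "),
         call. = FALSE)
  sel <- unique(c("variant_id", columns))
  sql <- paste0("SELECT ", paste0('"', sel, '"', collapse = ", "),
                " FROM variants")
  if (!is.null(where) && nzchar(trimws(where))) {
    where <- validate_filter(avail, where)
    sql <- paste0(sql, " WHERE ", where)
  }
  sql <- paste0(sql, " ORDER BY variant_id")
  DBI::dbGetQuery(h$con, sql)
}

#' Fetch per-variant genotype vectors
#'
#' Decompresses the stored genotype class / depth / alt-allele-frequency
#' vectors into matrices (variants x samples, in stored sample order).
#'
#' @param db Database path or connection.
#' @param variant_ids Optional integer vector restricting which variants to
#'   fetch; default all.
#' @return A list with `variant_id`, `samples`, and numeric matrices
#'   `gt_types`, `gt_depths`, `gt_alt_freqs` (rownames = variant_id).
#' @export
fetch_genotypes <- function(db, variant_ids = NULL) {
  h <- db_connect(db)
  if (h$own) on.exit(DBI::dbDisconnect(h$con), add = TRUE)
  sql <- "SELECT variant_id, gt_types, gt_depths, gt_alt_freqs FROM variants"
  if (!is.null(variant_ids)) {
    if (length(variant_ids) == 0L) {
      smp <- DBI::dbGetQuery(h$con, "SELECT name FROM samples ORDER BY sample_id")$name
      empty <- matrix(numeric(0), 0L, length(smp), dimnames = list(NULL, smp))
      return(list(variant_id = integer(0), samples = smp,
                  gt_types = empty, gt_depths = empty, gt_alt_freqs = empty))
    }
    sql <- paste0(sql, " WHERE variant_id IN (",
                  paste(as.integer(variant_ids), collapse = ","), ")")
  }
  sql <- paste0(sql, " ORDER BY variant_id")
  r <- DBI::dbGetQuery(h$con, sql)
  smp <- DBI::dbGetQuery(h$con, "SELECT name FROM samples ORDER BY sample_id")$name
  dec <- function(col) {
    m <- do.call(rbind, lapply(r[[col]], blob_decode))
    dimnames(m) <- list(r$variant_id, smp)
    m
  }
  list(variant_id = r$variant_id, samples = smp,
       gt_types = dec("gt_types"), gt_depths = dec("gt_depths"),
       gt_alt_freqs = dec("gt_alt_freqs"))
}
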