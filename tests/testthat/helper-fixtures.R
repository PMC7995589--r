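# Shared fixtures and independent oracles.
#
# The hand-built fixture is a 4-sample cohort (N1 at time 0; T1,T2,T3 at
# times 1..3, all patient p1) with variants whose allele fractions are exact
# (AD over DP 100) so every tool predicate can be checked by hand. Spread
# over chr1/chr2/chr10 to exercise numeric-aware contig ordering.

fixture_env <- new.env(parent = emptyenv())

# rows: name, chrom, pos, afs (N1,T1,T2,T3), annotations
fixture_rows <- function() {
  rows <- list(
    #        name           chrom   pos  N1    T1    T2    T3
    list("riser",           "chr1", 100, 0.00, 0.05, 0.15, 0.40),
    list("flat",            "chr1", 200, 0.00, 0.30, 0.30, 0.30),
    list("germline_riser",  "chr1", 300, 0.50, 0.55, 0.60, 0.75),
    list("loh",             "chr1", 400, 0.48, 0.97, 1.00, 1.00),
    list("loh_fail",        "chr1", 500, 0.48, 0.97, 0.55, 1.00),
    list("truncal",         "chr2", 100, 0.00, 0.20, 0.35, 0.40),
    list("truncal_boundary","chr2", 200, 0.04, 0.20, 0.30, 0.30),
    list("unique23",        "chr2", 300, 0.00, 0.00, 0.30, 0.25),
    list("unique_fail",     "chr2", 400, 0.00, 0.30, 0.00, 0.25),
    list("subthresh",       "chr10", 100, 0.00, 0.04, 0.00, 0.00),
    list("missing_af",      "chr10", 200, NA,   0.20, 0.30, 0.50),
    list("unique_near",     "chr10", 300, 0.00, 0.04, 0.30, 0.25),
    list("norm_leak",       "chr10", 400, 0.06, 0.30, 0.30, 0.30),
    list("riser_chr10",     "chr10", 500, 0.00, 0.10, 0.20, 0.40)
  )
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(name = r[[1]], chrom = r[[2]], pos = r[[3]],
               N1 = r[[4]], T1 = r[[5]], T2 = r[[6]], T3 = r[[7]],
               stringsAsFactors = FALSE)))
  df$impact <- ifelse(df$name %in% c("riser", "subthresh", "unique_fail"),
                      "LOW", "HIGH")
  df$cgi <- ifelse(df$name %in% c("flat", "loh_fail"), NA, "GENEX")
  df$civic_evi <- ifelse(df$name %in% c("riser", "truncal"), "A", NA)
  df
}

write_fixture_vcf <- function(path) {
  df <- fixture_rows()
  gt_of <- function(af) {
    if (is.na(af)) return("./.")
    if (af == 0) "0/0" else if (af >= 0.9) "1/1" else "0/1"
  }
  fmt <- function(af) {
    if (is.na(af)) return("./.:.:.")
    alt <- round(af * 100)
    sprintf("%s:100:%d,%d", gt_of(af), 100L - alt, alt)
  }
  recs <- vapply(seq_len(nrow(df)), function(i) {
    info <- c(paste0("gene=GENE_", df$name[i]),
              paste0("impact_severity=", df$impact[i]),
              if (!is.na(df$cgi[i])) paste0("cgi_gene=", df$cgi[i]),
              if (!is.na(df$civic_evi[i]))
                paste0("civic_evi_level=", df$civic_evi[i]),
              paste0("ac=", round(df$T3[i] * 100), ",1"),
              paste0("Start=", df$pos[i]))
    paste(df$chrom[i], df$pos[i], ".", "A", "G", "50", "PASS",
          paste(info, collapse = ";"), "GT:DP:AD",
          paste(vapply(c(df$N1[i], df$T1[i], df$T2[i], df$T3[i]),
                       fmt, ""), collapse = "\t"),
          sep = "\t")
  }, "")
  # one multiallelic record (skipped at load) and one record without AD
  multi <- paste("chr2", 500, ".", "A", "G,T", "50", "PASS",
                 "gene=GENE_multi;impact_severity=HIGH", "GT:DP:AD",
                 paste(rep("0/1:100:50,25,25", 4), collapse = "\t"),
                 sep = "\t")
  no_ad <- paste("chr10", 600, ".", "C", "T", "50", "PASS",
                 "gene=GENE_no_ad;impact_severity=HIGH", "GT:DP",
                 paste(c("0/0:100", "0/1:100", "1/1:100", "0/1:100"),
                       collapse = "\t"),
                 sep = "\t")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=gene,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=impact_severity,Number=1,Type=String,Description=\"Impact\">",
    "##INFO=<ID=cgi_gene,Number=1,Type=String,Description=\"CGI gene\">",
    "##INFO=<ID=civic_evi_level,Number=1,Type=String,Description=\"CIViC level\">",
    "##INFO=<ID=ac,Number=A,Type=Integer,Description=\"Multi-valued\">",
    "##INFO=<ID=Start,Number=1,Type=Integer,Description=\"Collides with core column\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("##contig=<ID=", c("chr1", "chr2", "chr10"), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "N1", "T1", "T2", "T3"), collapse = "\t"))
  writeLines(c(hdr, recs[1:9], multi, recs[10:14], no_ad), path)
  path
}

write_fixture_manifest <- function(path) {
  writeLines(c(
    "family_id\tname\tpaternal_id\tmaternal_id\tsex\tphenotype\tpatient_id\ttime",
    "p1\tN1\t0\t0\t0\t0\tp1\t0",
    "p1\tT1\t0\t0\t0\t0\tp1\t1",
    "p1\tT2\t0\t0\t0\t0\tp1\t2",
    "p1\tT3\t0\t0\t0\t0\tp1\t3"), path)
  path
}

# build (once per session) the hand-built fixture database
fixture_db <- function() {
  if (!is.null(fixture_env$db) && file.exists(fixture_env$db))
    return(fixture_env$db)
  dir <- tempfile("fixture")
  dir.create(dir)
  vcf <- write_fixture_vcf(file.path(dir, "fix.vcf"))
  mf <- write_fixture_manifest(file.path(dir, "fix.manifest"))
  db <- file.path(dir, "fix.db")
  suppressWarnings(suppressMessages(load_db(vcf, mf, db)))
  fixture_env$db <- db
  fixture_env$vcf <- vcf
  fixture_env$manifest <- mf
  db
}

# fixture variant_id of a named row (ids follow load order, multiallelic
# record skipped)
fixture_id <- function(name) {
  nm <- c(fixture_rows()$name, "no_ad")
  match(name, nm)
}

## ---- independent plain-text VCF parser (round-trip oracle) ------------

parse_vcf_text <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(body[[1]], "\t", fixed = TRUE)[[1]]
  samples <- header[-(1:9)]
  info_defs <- grep("^##INFO=", lines, value = TRUE)
  info_types <- setNames(
    sub('.*Type=([A-Za-z]+).*', '\\1', info_defs),
    sub('.*ID=([^,]+).*', '\\1', info_defs))
  recs <- lapply(body[-1], function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    info <- list()
    if (f[[8]] != ".") {
      for (kv in strsplit(f[[8]], ";", fixed = TRUE)[[1]]) {
        eq <- regexpr("=", kv, fixed = TRUE)
        if (eq < 0) info[[kv]] <- TRUE
        else info[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
      }
    }
    keys <- strsplit(f[[9]], ":", fixed = TRUE)[[1]]
    geno <- lapply(f[-(1:9)], function(s) {
      v <- strsplit(s, ":", fixed = TRUE)[[1]]
      setNames(as.list(v[seq_along(keys)]), keys)
    })
    names(geno) <- samples
    list(chrom = f[[1]], pos = as.integer(f[[2]]), ref = f[[4]],
         alt = f[[5]], info = info, geno = geno)
  })
  list(samples = samples, info_types = info_types, records = recs)
}

# scalar AF estimator re-derived from first principles for the oracle
oracle_af_one <- function(gt, dp, ad) {
  alt <- ref <- NA_integer_
  if (!is.null(ad) && !is.na(ad) && ad != ".") {
    parts <- suppressWarnings(as.integer(strsplit(ad, ",")[[1]]))
    if (length(parts) >= 2) { ref <- parts[[1]]; alt <- parts[[2]] }
  }
  dpv <- if (is.null(dp) || is.na(dp) || dp == ".") NA_integer_
         else as.integer(dp)
  total <- if (!is.na(dpv) && dpv > 0) dpv
           else if (!is.na(ref) && !is.na(alt)) ref + alt else NA_integer_
  if (!is.na(alt) && !is.na(total) && total > 0)
    return(min(alt / total, 1))
  al <- strsplit(gt, "[/|]")[[1]]
  if (length(al) && !any(al %in% c(".", ""))) {
    if (is.na(alt)) {  # dosage fallback only when AD is absent
      n_alt <- sum(al != "0")
      return(n_alt / length(al))
    }
  }
  -1
}

## ---- brute-force tool oracles ------------------------------------------

# plain-loop evaluation of each tool's predicate, independent of run_tool
brute_tool <- function(db, tool, params = tool_params(), filter = NULL) {
  rows <- fetch_variants(db, columns = c("chrom", "start", "is_somatic"),
                         where = filter)
  if (params$somatic_only) rows <- rows[rows$is_somatic == 1, ]
  am <- af_matrix(db, samples = params$samples, purity = params$purity,
                  variant_ids = rows$variant_id)
  cohort <- db_cohort(db)
  hits <- integer(0)
  for (p in unique(am$patient_id)) {
    pidx <- which(am$patient_id == p)
    times <- am$times[pidx]
    snames <- am$samples[pidx]
    for (k in seq_along(am$variant_id)) {
      afs <- am$afs[k, pidx]
      dps <- am$depths[k, pidx]
      if (any(afs < 0)) next
      if (params$minDP > 0 && any(dps < params$minDP)) next
      nrm <- afs[times == 0]
      tum <- afs[times > 0]
      pass <- switch(tool,
        bottleneck = {
          tt <- times[times > 0]
          if (length(tt) < 2 || length(unique(tt)) < 2) FALSE
          else {
            sl <- unname(coef(lm(tum ~ tt))[2])
            sl > params$minSlope && all(nrm <= params$maxNorm)
          }
        },
        loh = all(nrm >= params$hetLo & nrm <= params$hetHi) &&
          length(tum) > 0 &&
          all(pmin(tum, 1 - tum) <= params$lohTumorDelta),
        truncal = all(nrm <= params$maxNorm) && length(tum) > 0 &&
          all(tum > params$maxNorm),
        unique = {
          sp <- snames %in% params$specific
          any(sp) && all(afs[sp] > params$minAF) &&
            all(afs[!sp] <= params$maxOthers)
        },
        stop("unknown tool"))
      if (isTRUE(pass)) hits <- c(hits, am$variant_id[k])
    }
  }
  sort(unique(hits))
}

brute_set_somatic <- function(db, minDP, normAF, tumorAF, purity = FALSE) {
  am <- af_matrix(db, purity = purity)
  flagged <- integer(0)
  for (p in unique(am$patient_id)) {
    pidx <- which(am$patient_id == p)
    times <- am$times[pidx]
    if (!any(times == 0) || !any(times > 0)) next
    for (k in seq_along(am$variant_id)) {
      afs <- am$afs[k, pidx]
      dps <- am$depths[k, pidx]
      if (minDP > 0 && any(dps < minDP)) next
      nrm <- afs[times == 0]
      tum <- afs[times > 0]
      if (any(nrm < 0) || any(nrm > normAF)) next
      if (any(tum >= 0 & tum >= tumorAF))
        flagged <- c(flagged, am$variant_id[k])
    }
  }
  sort(unique(flagged))
}

# a simulated single-patient database; cached per (tag) in the session
sim_db <- function(tag, cfg) {
  key <- paste0("sim_", tag)
  if (!is.null(fixture_env[[key]]) && file.exists(fixture_env[[key]]$db))
    return(fixture_env[[key]])
  dir <- tempfile(paste0("sim", tag))
  dir.create(dir)
  r <- simulate_cohort(cfg, file.path(dir, "sim"))
  db <- file.path(dir, "sim.db")
  suppressWarnings(suppressMessages(load_db(r$vcf, r$manifest, db)))
  out <- list(db = db, sim = r)
  fixture_env[[key]] <- out
  out
}

truth_key <- function(df) paste(df$chrom, df$start, df$ref, df$alt)

# structured random annotation filter: rendered to SQL for the engine and
# evaluated natively in R (SQL three-valued NULL logic matches R's NA
# logic under & and |; rows where the whole expression is not TRUE are out)
random_filter <- function(rows) {
  clause <- function() {
    switch(sample(4L, 1L),
      {
        v <- sample(c("HIGH", "MED", "LOW"), 1L)
        op <- sample(c("=", "!="), 1L)
        list(sql = sprintf("impact_severity %s '%s'", op, v),
             mask = if (op == "=") rows$impact_severity == v
                    else rows$impact_severity != v)
      },
      list(sql = "cgi_gene != ''",
           mask = !is.na(rows$cgi_gene) & rows$cgi_gene != ""),
      {
        v <- sample(c("A", "B", "C"), 1L)
        list(sql = sprintf("civic_gene_max_level == '%s'", v),
             mask = rows$civic_gene_max_level == v)
      },
      {
        x <- round(runif(1L, 0, 5), 2)
        op <- sample(c(">=", "<", ">"), 1L)
        list(sql = sprintf("civic_gene_max_rating %s %s", op, x),
             mask = do.call(op, list(rows$civic_gene_max_rating, x)))
      })
  }
  n <- sample(1:3, 1L)
  cl <- replicate(n, clause(), simplify = FALSE)
  sql <- cl[[1L]]$sql
  mask <- cl[[1L]]$mask
  if (n > 1L) for (k in 2:n) {
    op <- sample(c("and", "or"), 1L)
    # parenthesize so SQL grouping stays left-associative like the R fold
    sql <- paste0("(", sql, ") ", op, " ", cl[[k]]$sql)
    mask <- if (op == "and") mask & cl[[k]]$mask else mask | cl[[k]]$mask
  }
  list(sql = sql, mask = !is.na(mask) & mask)
}
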