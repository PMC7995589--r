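# SQL query interface and annotation-filter validation.
#
# Filter expressions are SQL WHERE fragments over variant-table columns
# (comparisons, AND/OR, parentheses, string literals). They are validated
# against the existing columns before execution, and the emptiness idiom
# `col != ''` is rewritten to `(col IS NOT NULL AND col != '')` so that
# un-annotated rows (NULL) are excluded, matching the intended meaning of
# e.g. `cgi_gene != ''` ("the variant's gene is in the CGI catalog").

SQL_KEYWORDS <- c("and", "or", "not", "is", "null", "in", "like", "glob",
                  "between", "exists", "case", "when", "then", "else",
                  "true", "false")
WRITE_KEYWORDS <- c("insert", "update", "delete", "drop", "create", "alter",
                    "attach", "detach", "pragma", "replace", "vacuum",
                    "reindex")

# mask string literals with spaces so identifier scans ignore them
mask_strings <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  out <- chars
  in_str <- FALSE
  for (i in seq_along(chars)) {
    if (chars[[i]] == "'") {
      in_str <- !in_str
      out[[i]] <- " "
    } else if (in_str) out[[i]] <- " "
  }
  paste(out, collapse = "")
}

filter_identifiers <- function(expr) {
  masked <- mask_strings(expr)
  toks <- regmatches(masked,
                     gregexpr("[A-Za-z_][A-Za-z0-9_]*", masked))[[1L]]
  setdiff(unique(tolower(toks)), SQL_KEYWORDS)
}

# validate a WHERE fragment and apply the NULL-aware emptiness rewrite
validate_filter <- function(available, expr) {
  ids <- filter_identifiers(expr)
  bad <- setdiff(ids, tolower(available))
  if (length(bad))
    stop("unknown column(s) in filter: ", paste(bad, collapse = ", "),
         "; available columns: ", paste(available, collapse = ", "),
         call. = FALSE)
  masked <- mask_strings(expr)
  if (grepl(";", masked, fixed = TRUE))
    stop("filter must be a single expression (no ';')", call. = FALSE)
  wr <- regmatches(masked, gregexpr("[A-Za-z_][A-Za-z0-9_]*", masked))[[1L]]
  hit <- intersect(tolower(wr), WRITE_KEYWORDS)
  if (length(hit))
    stop("filter contains disallowed keyword(s): ",
         paste(hit, collapse = ", "), call. = FALSE)
  rewrite_empty_tests(expr)
}

# col != '' -> (col IS NOT NULL AND col != '')
rewrite_empty_tests <- function(expr) {
  gsub("([A-Za-z_][A-Za-z0-9_]*)\\s*!=\\s*''",
       "(\\1 IS NOT NULL AND \\1 != '')", expr)
}

#' Run a read-only SQL query against a variant database
#'
#' Executes a single `SELECT` statement over the database tables (`variants`,
#' `samples`, `meta`). Anything other than a read-only query — write
#' statements, multiple statements — is rejected. On an unknown-column error
#' the message is augmented with the list of valid variant-table columns.
#'
#' @param db Database path or connection.
#' @param sql Query text, e.g.
#'   `"select chrom, start, end, ref, alt, gene from variants where
#'   civic_evi_level = 'A'"`.
#' @return A data.frame of result rows (possibly zero rows).
#' @export
run_query <- function(db, sql) {
  stopifnot(is.character(sql), length(sql) == 1L)
  h <- db_connect(db)
  if (h$own) on.exit(DBI::dbDisconnect(h$con), add = TRUE)

  stmt <- trimws(sql)
  stmt <- sub(";\\s*$", "", stmt)
  masked <- mask_strings(stmt)
  if (grepl(";", masked, fixed = TRUE))
    stop("only a single SQL statement is allowed", call. = FALSE)
  first <- tolower(sub("^\\s*([A-Za-z]+).*$", "\\1", stmt))
  if (!first %in% c("select", "with"))
    stop("only read-only SELECT queries are allowed, got: ", first,
         call. = FALSE)
  toks <- tolower(regmatches(masked,
                             gregexpr("[A-Za-z_][A-Za-z0-9_]*", masked))[[1L]])
  hit <- intersect(toks, WRITE_KEYWORDS)
  if (length(hit))
    stop("query contains disallowed keyword(s): ",
         paste(hit, collapse = ", "), call. = FALSE)

  tryCatch(DBI::dbGetQuery(h$con, stmt),
           error = function(e) {
             avail <- setdiff(DBI::dbListFields(h$con, "variants"),
                              BLOB_COLUMNS)
             stop(conditionMessage(e), "\nvalid variant columns: ",
                  paste(avail, collapse = ", "), call. = FALSE)
           })
}
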