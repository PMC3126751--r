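#' Read a tabular isotopologue dataset
#'
#' Accepts comma- or tab-separated files (auto-detected from the header
#' line, or forced with `dialect`). The table must contain a `time` column
#' and intensity columns `m0..mN`; a `replicate` column and any other
#' columns are preserved. Lines starting with `#` are provenance comments
#' and are skipped. All validation problems (non-numeric cells with their
#' row and column, negative intensities, duplicate time/replicate keys,
#' missing `m0`) are collected and reported together.
#'
#' @param path file path.
#' @param dialect `"auto"` (default), `"csv"` or `"tsv"`.
#' @return a data.frame with columns `time`, optional `replicate`, then
#'   `m0..mN` (attribute `mass_columns` lists them).
#' @export
read_isotopologue_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty table: ", path, call. = FALSE)
  sep <- switch(dialect, csv = ",", tsv = "\t",
                auto = if (grepl("\t", lines[1L])) "\t" else ",")
  df <- read.csv(text = paste(lines, collapse = "\n"), sep = sep,
                 check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = "character", strip.white = TRUE)
  problems <- character(0)
  if (!"time" %in% names(df)) problems <- c(problems, "missing 'time' column")
  mass_cols <- grep("^m[0-9]+$", names(df), value = TRUE)
  if (!"m0" %in% mass_cols) problems <- c(problems, "missing 'm0' column")
  mass_cols <- mass_cols[order(as.integer(sub("^m", "", mass_cols)))]
  num_cols <- intersect(c("time", mass_cols), names(df))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & nzchar(df[[cn]]))
    if (length(bad))
      problems <- c(problems, sprintf("non-numeric value '%s' at row %d, column %s",
                                      df[[cn]][bad[1L]], bad[1L], cn))
    df[[cn]] <- v
  }
  if (!length(problems)) {
    neg <- which(sapply(df[mass_cols], function(v) any(v < 0, na.rm = TRUE)))
    if (length(neg))
      problems <- c(problems, paste("negative intensities in column(s)",
                                    paste(mass_cols[neg], collapse = ", ")))
    if (any(!is.finite(df$time)) || any(df$time < 0))
      problems <- c(problems, "time must be non-negative and numeric")
    key <- if ("replicate" %in% names(df))
      paste(df$time, df$replicate) else as.character(df$time)
    if (anyDuplicated(key))
      problems <- c(problems, "duplicate time/replicate keys")
  }
  if (length(problems))
    stop("invalid isotopologue table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  ord <- c("time", intersect("replicate", names(df)), mass_cols,
           setdiff(names(df), c("time", "replicate", mass_cols)))
  df <- df[, ord, drop = FALSE]
  attr(df, "mass_columns") <- mass_cols
  df
}

#' Write a tabular isotopologue dataset
#'
#' Writes tab-separated (default) or comma-separated text with a provenance
#' comment header (tool version, optional seed) and stable column order
#' (`time`, `replicate` if present, then `m0..mN`). Floats are written at
#' full precision, so a write/read round trip reproduces the table.
#'
#' @param table a data.frame as returned by [read_isotopologue_table()].
#' @param path output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param seed optional seed to record in the provenance header.
#' @export
write_isotopologue_table <- function(table, path, dialect = c("tsv", "csv"),
                                     seed = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  mass_cols <- grep("^m[0-9]+$", names(table), value = TRUE)
  mass_cols <- mass_cols[order(as.integer(sub("^m", "", mass_cols)))]
  ord <- c(intersect(c("time", "replicate"), names(table)), mass_cols,
           setdiff(names(table), c("time", "replicate", mass_cols)))
  header <- c(sprintf("# moietyfit %s",
                      as.character(utils::packageVersion("moietyfit"))),
              if (!is.null(seed)) sprintf("# seed %d", as.integer(seed)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(format(table[, ord, drop = FALSE], digits = 17, trim = TRUE,
                     scientific = FALSE),
              con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a moiety model definition from JSON
#'
#' The file declares `name` and a `subunits` array of
#' `{name, carbon_count, allowed_labels, parameter_names}` objects. The
#' shipped `udp_glcnac.json` reproduces the default 6-parameter UDP-GlcNAc
#' model.
#'
#' @param path JSON file path; defaults to the shipped UDP-GlcNAc model.
#' @return a [moiety_space()].
#' @examples
#' read_moiety_model()  # the shipped UDP-GlcNAc definition
#' @export
read_moiety_model <- function(path = system.file("extdata", "udp_glcnac.json",
                                                 package = "moietyfit")) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$subunits) || !NROW(cfg$subunits))
    stop("model definition must declare subunits", call. = FALSE)
  subs <- if (is.data.frame(cfg$subunits))
    lapply(seq_len(nrow(cfg$subunits)), function(i) as.list(cfg$subunits[i, ]))
  else cfg$subunits
  moiety_space(lapply(subs, function(s)
    moiety_subunit(s$name[[1]], s$carbon_count[[1]],
                   unlist(s$allowed_labels),
                   unlist(s$parameter_names))),
    name = if (is.null(cfg$name)) "metabolite" else cfg$name)
}

#' Read a variant grammar from JSON
#'
#' The file maps subunit names to arrays of alternative allowed-label sets,
#' e.g. `{"acetyl": [[0, 1, 2]]}`.
#'
#' @param path JSON file path; defaults to the shipped UDP-GlcNAc grammar.
#' @return a named list suitable for [generate_variants()].
#' @export
read_variant_grammar <- function(path = system.file("extdata",
                                                    "variant_grammar.json",
                                                    package = "moietyfit")) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(g, function(alts) lapply(alts, function(a) as.integer(unlist(a))))
}
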