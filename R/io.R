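#' Read a hypoxia time-series table
#'
#' Reads a delimited table in the training layout: a header row, a time
#' column (`time (hours)` or `time`), and one numeric column per observed
#' series. Blank cells become missing values. Rows are sorted by time;
#' duplicate times, non-numeric cells and a missing 0 h row are reported
#' with row numbers.
#'
#' @param path File path.
#' @param sep Field separator (default tab; use "," for CSV).
#' @return data.frame with the time column first.
#' @export
read_timeseries <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = c("", "NA"))
  if (nrow(raw) == 0) stop("no data rows in ", path)
  tcol <- .time_column(raw)
  for (cn in names(raw)) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(!is.na(raw[[cn]]) & is.na(v))
    if (length(bad))
      stop("non-numeric cell(s) in column '", cn, "', data row(s) ",
           paste(bad, collapse = ", "))
    raw[[cn]] <- v
  }
  if (anyNA(raw[[tcol]])) stop("missing time value(s)")
  dup <- duplicated(raw[[tcol]])
  if (any(dup))
    stop("duplicate time(s) at data row(s) ",
         paste(which(dup), collapse = ", "))
  raw <- raw[order(raw[[tcol]]), , drop = FALSE]
  rownames(raw) <- NULL
  if (!any(raw[[tcol]] == 0)) stop("table must contain a 0 h row")
  raw
}

#' Read an initial-condition table
#'
#' Reads a two-column `species`/`value` table in the layout of the final
#' model's initial-condition list. `HRE1` and `HRE2` entries are the motif
#' counts (doubling as the free-HRE initial concentrations); an `O2` entry
#' sets the boundary oxygen level; `HIF1A_protein_total` and
#' `HIF2A_protein_total` entries are accepted but ignored, because the
#' totals are derived quantities. Unknown species names are rejected.
#' Species absent from the table default to 0.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return List: `state` (named vector over [hif_species()]), `hre1`,
#'   `hre2`, `o2`.
#' @export
read_initial_conditions <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("species", "value") %in% names(tab)))
    stop("initial-condition table needs columns 'species' and 'value'")
  derived <- c("HIF1A_protein_total", "HIF2A_protein_total")
  known <- c(.HIF_SPECIES, derived, "O2")
  unknown <- setdiff(tab$species, known)
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "))
  if (any(duplicated(tab$species)))
    stop("duplicate species entries")
  v <- stats::setNames(as.numeric(tab$value), tab$species)
  if (anyNA(v)) stop("non-numeric value(s) in initial-condition table")
  if (any(v[setdiff(names(v), derived)] < 0))
    stop("initial concentrations must be non-negative")
  required <- c("HIF1A_mrna", "HIF2A_mrna", "HIF1A_protein", "HIF2A_protein",
                "PHD_protein", "HIF1B", "Gene_mRNA")
  miss <- setdiff(required, names(v))
  if (length(miss))
    stop("missing required species: ", paste(miss, collapse = ", "))
  state <- stats::setNames(numeric(length(.HIF_SPECIES)), .HIF_SPECIES)
  present <- intersect(names(v), .HIF_SPECIES)
  state[present] <- v[present]
  list(state = state,
       hre1 = if ("HRE1" %in% names(v)) unname(v[["HRE1"]]) else 0,
       hre2 = if ("HRE2" %in% names(v)) unname(v[["HRE2"]]) else 0,
       o2 = if ("O2" %in% names(v)) unname(v[["O2"]]) else 1)
}

#' Read/write a parameter table
#'
#' Parameter tables are TSV with columns `name`, `value` and optionally
#' `free` (logical flag from a fit).
#'
#' @param path File path.
#' @return Named numeric vector.
#' @export
read_params <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "value") %in% names(tab)))
    stop("parameter table needs columns 'name' and 'value'")
  stats::setNames(as.numeric(tab$value), tab$name)
}

#' @rdname read_params
#' @param params Named numeric vector.
#' @param free Optional character vector of free parameter names.
#' @export
write_params <- function(params, path, free = NULL) {
  tab <- data.frame(name = names(params), value = unname(params))
  if (!is.null(free)) tab$free <- tab$name %in% free
  utils::write.table(format(tab, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.format_table <- function(df, digits = 4) {
  out <- df
  for (cn in names(out))
    if (is.numeric(out[[cn]]))
      out[[cn]] <- ifelse(is.na(out[[cn]]), "",
                          formatC(out[[cn]], format = "f", digits = digits))
  out
}

#' Write pipeline outputs with a checksum manifest
#'
#' Writes every element of `results` (data.frames, trajectories, named
#' numeric vectors) as a TSV under `out_dir` with deterministic names
#' (`<name>.tsv`), numbers formatted to 4 decimal places (the training
#' table convention). With `full_precision = TRUE`, a `<name>_full.tsv`
#' sidecar at 15 significant digits is written alongside, which
#' round-trips through [read_timeseries()] to 1e-12. A `manifest.tsv`
#' listing every artifact with its MD5 checksum is written last.
#'
#' @param results Named list of tabular results.
#' @param out_dir Output directory (created if needed).
#' @param full_precision Also write full-precision sidecars.
#' @return The manifest data.frame (`file`, `md5`), invisibly written to
#'   `manifest.tsv`.
#' @export
write_outputs <- function(results, out_dir, full_precision = FALSE) {
  if (is.null(names(results)) || any(names(results) == ""))
    stop("results must be a fully named list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("directory not writable: ", out_dir)
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.numeric(x) && !is.null(names(x)))
      x <- data.frame(name = names(x), value = unname(x))
    if (!is.data.frame(x)) stop("result '", nm, "' is not tabular")
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(.format_table(x), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
    if (full_precision) {
      ff <- file.path(out_dir, paste0(nm, "_full.tsv"))
      xf <- x
      for (cn in names(xf))
        if (is.numeric(xf[[cn]]))
          xf[[cn]] <- ifelse(is.na(xf[[cn]]), "",
                             formatC(xf[[cn]], format = "g", digits = 15))
      utils::write.table(xf, ff, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, ff)
    }
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}

#' Paths to the packaged training fixtures
#'
#' The ELISA absolute-concentration table, the hypoxia time-series table
#' and the final-model initial-condition table are shipped as plain-text
#' fixtures.
#'
#' @param which `"elisa"`, `"timeseries"` or `"initial_conditions"`.
#' @return File path.
#' @export
hif_fixture <- function(which = c("elisa", "timeseries",
                                  "initial_conditions")) {
  which <- match.arg(which)
  fn <- switch(which,
               elisa = "table1_elisa.tsv",
               timeseries = "table2_timeseries.tsv",
               initial_conditions = "table3_initial_conditions.tsv")
  system.file("extdata", fn, package = "hifdyn", mustWork = TRUE)
}

#' Read the ELISA absolute-concentration table
#'
#' @param path File path (default: packaged fixture).
#' @return data.frame with columns `protein`, `condition`, `time_h`,
#'   `absolute_ng_per_mg`.
#' @export
read_elisa <- function(path = hif_fixture("elisa")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "condition", "time_h", "absolute_ng_per_mg")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("ELISA table lacks column(s): ",
                         paste(miss, collapse = ", "))
  tab
}
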