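#' Load a scenario/configuration file
#'
#' Reads a structured-text (YAML) configuration and returns the validated
#' scenario object. The file must carry a `type` key (`suspension`,
#' `tissue` or `ascites`); all remaining keys must be constructor
#' arguments of the corresponding scenario type — unknown keys are
#' rejected with a message listing them.
#'
#' @param path file path.
#' @return A [suspension_scenario()], [tissue_config()] or
#'   [ascites_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(raw$type)) {
    stop("configuration must be a YAML map with a 'type' key",
         call. = FALSE)
  }
  type <- raw$type
  raw$type <- NULL
  ctor <- switch(type,
                 suspension = suspension_scenario,
                 tissue = tissue_config,
                 ascites = ascites_config,
                 stop("unknown configuration type: ", type, call. = FALSE))
  extra <- character(0)
  if (type == "suspension" && !is.null(raw$doses)) {
    extra <- "doses"
    doses <- raw$doses
    raw$doses <- NULL
  }
  known <- names(formals(ctor))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  obj <- do.call(ctor, raw)
  if (length(extra)) attr(obj, "doses") <- as.numeric(doses)
  obj
}

#' Write a scenario/configuration file
#'
#' Serializes a scenario object back to YAML such that
#' [load_config()] reproduces it (round-trip identity up to the derived
#' sampling grid).
#'
#' @param x a scenario object.
#' @param path output file path.
#' @export
write_config <- function(x, path) {
  type <- if (inherits(x, "suspension_scenario")) "suspension"
  else if (inherits(x, "tissue_config")) "tissue"
  else if (inherits(x, "ascites_config")) "ascites"
  else stop("not a scenario object", call. = FALSE)
  lst <- unclass(x)
  lst$sampling <- NULL
  out <- c(list(type = type), lst)
  if (!is.null(attr(x, "doses"))) out$doses <- attr(x, "doses")
  out <- lapply(out, function(v) if (is.numeric(v)) unname(v) else v)
  yaml::write_yaml(out, path)
  invisible(path)
}

# units for worksheet columns
column_unit <- function(nm) {
  units <- c(time = "s", glc = "uM", o2 = "uM", fbp = "uM", atp = "uM",
             a_pool = "uM", pi_ = "uM", nadh = "uM", pyr = "uM",
             lac = "uM", adp = "uM", nad = "uM", f_active = "fraction",
             cum_glc = "umol/l cell water", cum_lac = "umol/l cell water",
             cum_o2 = "umol/l cell water",
             cum_sink = "umol/l cell water",
             cum_mito = "umol/l cell water",
             j_head = "uM/s (6C)", j_tail = "uM/s (3C)",
             j_oxphos_atp = "uM/s ATP", j_o2 = "uM/s O2",
             j_ldh = "uM/s", j_hyd = "uM/s ATP", j_pool_loss = "uM/s",
             j_sink = "uM/s (6C)", j_mito = "uM/s (3C)",
             j_pool_resyn = "uM/s",
             fbp_content = "umol/ml cell volume",
             atp_content = "umol/ml cell volume",
             cum_glc_content = "umol/ml cell volume",
             cum_lac_content = "umol/ml cell volume",
             flow = "ml/l cell water/s", layer = "index",
             cell_type = "index", atp_syn_ox = "uM/s ATP",
             atp_syn_glyc_throughput = "uM/s ATP",
             atp_syn_glyc_store = "uM/s ATP", vessel_glc = "uM",
             vessel_o2 = "uM", vessel_lac = "uM", distance = "um")
  out <- unname(units[nm])
  out[is.na(out)] <- "-"
  out
}

#' Export a simulation result as a worksheet
#'
#' Writes a CSV mirroring the published simulation worksheets: a header
#' row with column names, a second row with units, then the data at full
#' precision in a deterministic column order.
#'
#' @param result a data frame (e.g. a `suspension_sim` or one layer of a
#'   tissue result).
#' @param path output CSV path.
#' @param columns optional character vector selecting and ordering
#'   columns (default: all, in their current order).
#' @return `path`, invisibly.
#' @export
write_worksheet <- function(result, path, columns = NULL) {
  stopifnot(is.data.frame(result))
  if (!is.null(columns)) {
    miss <- setdiff(columns, names(result))
    if (length(miss)) {
      stop("result lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    result <- result[, columns, drop = FALSE]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(result), collapse = ","), con)
  writeLines(paste(column_unit(names(result)), collapse = ","), con)
  if (nrow(result)) {
    utils::write.table(
      format(as.data.frame(result), digits = 17, trim = TRUE,
             scientific = FALSE),
      con, sep = ",", col.names = FALSE, row.names = FALSE,
      quote = FALSE)
  }
  invisible(path)
}

#' Read back a worksheet written by [write_worksheet()]
#'
#' @param path CSV path.
#' @return Tibble with a `units` attribute (named character vector).
#' @export
read_worksheet <- function(path) {
  header <- strsplit(readLines(path, n = 2), ",")
  df <- utils::read.csv(path, skip = 2, header = FALSE,
                        col.names = header[[1]])
  df <- tibble::as_tibble(df)
  attr(df, "units") <- stats::setNames(header[[2]], header[[1]])
  df
}
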