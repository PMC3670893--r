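#' Read or write a brood-census table
#'
#' The on-disk census format is a plain CSV with one row per brood and
#' two integer columns, `males` and `females`: the adult wasps of each
#' sex that emerged from that host. Brood classes are derived on read
#' (all-male, all-female, mixed-sex); rows with no emergers are dropped.
#' Additional columns are preserved in the per-brood records but ignored
#' by the estimators.
#'
#' @param path CSV file path.
#' @return `read_brood_census()`: a [brood_census()].
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write.csv(data.frame(males = c(30, 0, 12), females = c(0, 44, 31)),
#'           p, row.names = FALSE)
#' read_brood_census(p)
#' @export
read_brood_census <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("males", "females") %in% names(d))) {
    stop("census table must have columns 'males' and 'females'",
         call. = FALSE)
  }
  d$males <- as.integer(d$males)
  d$females <- as.integer(d$females)
  if (any(is.na(d$males)) || any(is.na(d$females)) ||
      any(d$males < 0) || any(d$females < 0)) {
    stop("census counts must be non-negative integers", call. = FALSE)
  }
  d <- d[d$males + d$females > 0L, , drop = FALSE]
  d$class <- ifelse(d$males > 0L & d$females > 0L, "mixed",
                    ifelse(d$males > 0L, "male", "female"))
  brood_census(
    n_male_broods = sum(d$class == "male"),
    n_female_broods = sum(d$class == "female"),
    n_mixed_broods = sum(d$class == "mixed"),
    wasps_in_male_broods = sum(d$males[d$class == "male"]),
    wasps_in_female_broods = sum(d$females[d$class == "female"]),
    wasps_in_mixed_broods = sum(d$males[d$class == "mixed"] +
                                  d$females[d$class == "mixed"]),
    broods = d
  )
}

#' @rdname read_brood_census
#' @param census A [brood_census()] with per-brood records (e.g. from
#'   [generate_brood_census()]).
#' @export
write_brood_census <- function(census, path) {
  b <- census$broods
  if (is.null(b)) stop("census carries no per-brood records", call. = FALSE)
  utils::write.csv(b, path, row.names = FALSE)
  invisible(path)
}

#' Write per-generation simulation statistics as CSV
#'
#' One row per generation: eggs and adults by sex, premature host
#' deaths, the extinction flag, and one `strategy_<i>` adult-count
#' column per founder strategy. Comma-separated, header row, UTF-8,
#' `.` decimal.
#'
#' @param sim A `"wasp_sim"` from [run_simulation()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(sim, path) {
  st <- sim$stats
  fr <- sim$freq
  if (!is.null(fr) && nrow(fr) == nrow(st)) {
    colnames(fr) <- paste0("strategy_", seq_len(ncol(fr)))
    st <- cbind(st, fr)
  }
  utils::write.csv(st, path, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' A small JSON record written beside every command-line run: the
#' command, the fully resolved configuration, the seed, the package
#' version, a timestamp and the list of output files. Re-running the
#' package with the configuration and seed of a manifest reproduces the
#' run's outputs bit for bit (the timestamp aside).
#'
#' @param command Name of the command that produced the outputs.
#' @param config The resolved [simulation_config()] (or arbitrary
#'   parameter list) of the run.
#' @param seed The seed the run used.
#' @param outputs Character vector of output file paths.
#' @return `run_manifest()`: a `"run_manifest"` list.
#' @export
run_manifest <- function(command, config, seed, outputs = character()) {
  structure(list(
    command = command,
    config = if (inherits(config, "simulation_config")) unclass(config)
             else config,
    seed = as.integer(seed),
    package_version = as.character(utils::packageVersion("polywasp")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `"run_manifest"`.
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
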