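# Internal population representation.
#
# Individuals are stored in parallel arrays (struct-of-arrays) so that a
# whole generation can be advanced with vectorized operations:
#   females: strat (n x K sex-choice matrix), mated, mate_strat (the
#            fertilizing male's sex-choice row; NA while virgin),
#            lineage (natal-clone id, the kin-recognition token),
#            anc (n x n_tags founder-ancestry weights)
#   males:   strat, lineage, anc, virgins_son, capacity (fertilizations
#            left; virility or virgin_son_virility at emergence)
#
# Ancestry weights record how much of an individual's (blended) strategy
# descends from each founder strategy: founders are one-hot, daughters
# receive w * father + (1 - w) * mother — exactly the recombination rule
# for the strategy values themselves — and sons copy their mother. A
# founder's "population share" is the mean ancestry weight over adults,
# which is also that founder's weight in the population-mean strategy.
# Because mate_strat/mate_anc rows are stored on the mated female, males
# of the parental generation never need to be revisited at laying time.
#
# Life-history constants shared by every individual in a run are carried
# once, on the strategy template, not per individual.

new_population <- function(keys,
                           f_strat, f_mated, f_mate_strat, f_mate_anc,
                           f_lineage, f_anc,
                           m_strat, m_lineage, m_anc, m_virgins_son,
                           m_capacity) {
  structure(list(
    keys = keys,
    n_tags = ncol(f_anc),
    females = list(n = nrow(f_strat), strat = f_strat, mated = f_mated,
                   mate_strat = f_mate_strat, mate_anc = f_mate_anc,
                   lineage = f_lineage, anc = f_anc),
    males = list(n = nrow(m_strat), strat = m_strat, lineage = m_lineage,
                 anc = m_anc, virgins_son = m_virgins_son,
                 capacity = m_capacity)
  ), class = "wasp_population")
}

empty_population <- function(keys, n_tags) {
  K <- length(keys)
  m0 <- matrix(numeric(0), 0, K, dimnames = list(NULL, keys))
  a0 <- matrix(numeric(0), 0, n_tags)
  new_population(keys, m0, logical(0), m0, a0, integer(0), a0,
                 m0, integer(0), a0, logical(0), integer(0))
}

#' Build a founding population
#'
#' Creates the generation-0 adults for [run_simulation()]. Each strategy
#' contributes `counts[i]` founders; each founder is male with probability
#' `config$initial_sex_distribution` and founding females are virgin with
#' probability `config$initial_virgin_ratio`. Mated founding females are
#' treated as fertilized by a male of their own strategy, and every
#' founder is its own maternal lineage (founders are mutually unrelated).
#'
#' @param config A [simulation_config()].
#' @param strategies A [strategy()] or list of strategies; their
#'   `info_level` must match the configuration.
#' @param counts Founders per strategy; defaults to
#'   `config$initial_wasp_count` each.
#' @return A `"wasp_population"` object.
#' @examples
#' pop <- initial_population(simulation_config(), strategy())
#' population_size(pop)
#' @export
initial_population <- function(config, strategies,
                               counts = NULL) {
  validate_config(config)
  if (inherits(strategies, "wasp_strategy")) strategies <- list(strategies)
  n_s <- length(strategies)
  if (n_s < 1) stop("at least one strategy is required", call. = FALSE)
  if (is.null(counts)) counts <- rep(config$initial_wasp_count, n_s)
  counts <- as.integer(counts)
  if (length(counts) != n_s || any(counts < 0) || sum(counts) < 1) {
    stop("counts must give a non-negative founder count per strategy, ",
         "with at least one founder in total", call. = FALSE)
  }
  keys <- sex_choice_keys(config$info_level)
  for (s in strategies) {
    validate_strategy(s)
    if (!identical(names(s$sex_choice), keys)) {
      stop("strategy info_level does not match config$info_level",
           call. = FALSE)
    }
  }
  strat_all <- do.call(rbind, lapply(strategies, function(s) s$sex_choice))
  tag_all <- rep(seq_len(n_s), counts)
  n <- sum(counts)
  strat <- strat_all[tag_all, , drop = FALSE]
  colnames(strat) <- keys
  anc <- diag(n_s)[tag_all, , drop = FALSE]
  is_male <- stats::runif(n) < config$initial_sex_distribution
  lineage <- seq_len(n)

  fi <- which(!is_male)
  mi <- which(is_male)
  f_strat <- strat[fi, , drop = FALSE]
  f_anc <- anc[fi, , drop = FALSE]
  f_mated <- stats::runif(length(fi)) >= config$initial_virgin_ratio
  f_mate_strat <- matrix(NA_real_, length(fi), length(keys),
                         dimnames = list(NULL, keys))
  f_mate_anc <- matrix(NA_real_, length(fi), n_s)
  f_mate_strat[f_mated, ] <- f_strat[f_mated, , drop = FALSE]
  f_mate_anc[f_mated, ] <- f_anc[f_mated, , drop = FALSE]
  template <- strategies[[1]]
  new_population(
    keys,
    f_strat, f_mated, f_mate_strat, f_mate_anc, lineage[fi], f_anc,
    strat[mi, , drop = FALSE], lineage[mi], anc[mi, , drop = FALSE],
    rep(FALSE, length(mi)),
    rep(template$virility, length(mi))
  )
}

#' @rdname initial_population
#' @param pop A `"wasp_population"`.
#' @return `population_size()`: named integer vector with elements
#'   `females`, `males`.
#' @export
population_size <- function(pop) {
  c(females = pop$females$n, males = pop$males$n)
}

#' @export
print.wasp_population <- function(x, ...) {
  cat("<wasp_population>", x$females$n, "females,", x$males$n, "males;",
      x$n_tags, "founder strategies; info keys:",
      paste(x$keys, collapse = ", "), "\n")
  invisible(x)
}

# Founder-ancestry mass over all adults (sums to the number of adults).
ancestry_mass <- function(pop) {
  colSums(pop$females$anc) + colSums(pop$males$anc)
}

# Mean sex-choice vector over all adults: the strategy the population has
# blended to.
population_mean_strategy <- function(pop) {
  n <- pop$females$n + pop$males$n
  if (n == 0L) return(NULL)
  (colSums(pop$females$strat) + colSums(pop$males$strat)) / n
}

# Has recombination homogenized the population? True when every founder's
# ancestry weight varies by less than tol across all adults.
ancestry_converged <- function(pop, tol = 1e-3) {
  if (pop$females$n + pop$males$n == 0L) return(FALSE)
  for (j in seq_len(pop$n_tags)) {
    r <- range(pop$females$anc[, j], pop$males$anc[, j])
    if (r[2L] - r[1L] >= tol) return(FALSE)
  }
  TRUE
}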