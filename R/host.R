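#' Host objects
#'
#' A host is a container of eggs plus an alive flag. Eggs are recorded in
#' oviposition order with the identity of the laying female
#' (`mother_id`), her maternal lineage (`lineage`, the natal-clone
#' identifier used for kin recognition), and the egg's `sex`.
#'
#' @param eggs A data frame with columns `mother_id`, `lineage` and `sex`
#'   (`"male"`/`"female"`), one row per egg, or `NULL` for an empty host.
#' @param alive Logical; hosts die prematurely when overfilled.
#' @return An object of class `"wasp_host"`.
#' @examples
#' h <- host(data.frame(mother_id = 1, lineage = 1, sex = "male"))
#' host_egg_count(h)
#' @export
host <- function(eggs = NULL, alive = TRUE) {
  if (is.null(eggs)) {
    eggs <- data.frame(mother_id = integer(), lineage = integer(),
                       sex = character())
  }
  stopifnot(all(c("mother_id", "lineage", "sex") %in% names(eggs)),
            all(eggs$sex %in% c("male", "female")))
  structure(list(eggs = eggs, alive = isTRUE(alive)), class = "wasp_host")
}

#' @rdname host
#' @param x A `"wasp_host"`.
#' @export
host_egg_count <- function(x) nrow(x$eggs)

#' Host attractiveness
#'
#' Attractiveness starts at 1 for an empty host and declines linearly by
#' `egg_count_influence` for every egg already laid in it, floored at 0:
#' `max(0, 1 - egg_count_influence * eggs)`.
#'
#' @param x A [host()] object, or directly a non-negative egg count.
#' @param egg_count_influence Attractiveness decrement per egg.
#' @return Attractiveness in `[0, 1]`.
#' @examples
#' attractiveness(0, 0.5)
#' attractiveness(3, 0.5)
#' @export
attractiveness <- function(x, egg_count_influence) {
  n <- if (inherits(x, "wasp_host")) host_egg_count(x) else as.numeric(x)
  pmax(0, 1 - egg_count_influence * n)
}

#' Host acceptance
#'
#' A female accepts a host for oviposition iff its attractiveness
#' *strictly* exceeds her acceptance threshold. Low thresholds admit
#' already-parasitized hosts and therefore correspond to high levels of
#' superparasitism. Dead hosts are never accepted.
#'
#' @inheritParams attractiveness
#' @param threshold Acceptance threshold in `[0, 1]`.
#' @return Logical.
#' @examples
#' accept_host(host(), threshold = 0.99, egg_count_influence = 0.3)
#' accept_host(1, threshold = 0.7, egg_count_influence = 0.3)
#' @export
accept_host <- function(x, threshold, egg_count_influence) {
  if (inherits(x, "wasp_host") && !x$alive) return(FALSE)
  attractiveness(x, egg_count_influence) > threshold
}

# rel/sex classes -> key index within sex_choice_keys(info_level).
# rel, sexes in 1:3 = (related, unrelated, mixed) / (male, female, mixed).
state_key_index <- function(n_eggs, n_related, n_male, info_level) {
  if (n_eggs == 0) return(1L)
  switch(info_level,
    none = 2L,
    relatedness = {
      rel <- if (n_related == n_eggs) 1L else if (n_related == 0L) 2L else 3L
      1L + rel
    },
    sex_and_relatedness = {
      rel <- if (n_related == n_eggs) 1L else if (n_related == 0L) 2L else 3L
      sx <- if (n_male == n_eggs) 1L else if (n_male == 0L) 2L else 3L
      1L + (rel - 1L) * 3L + sx
    },
    stop("unknown info_level: ", info_level, call. = FALSE)
  )
}

#' Sense the state of a host
#'
#' Classifies a host from the point of view of an ovipositing female:
#' `"empty"`, or a parasitized state describing the kinship (relative to
#' the observer's maternal lineage) and sexes of the eggs already present,
#' coarsened to what the given information level can resolve. This is a
#' pure function of its arguments.
#'
#' @param x A living [host()].
#' @param observer_lineage The observer female's natal-clone (maternal
#'   lineage) identifier; eggs are "related" when laid by her or her
#'   clone-mates.
#' @param info_level See [sex_choice_keys()].
#' @return A single key name from `sex_choice_keys(info_level)`.
#' @examples
#' h <- host(data.frame(mother_id = 7, lineage = 7, sex = "male"))
#' host_state_key(h, observer_lineage = 1, "sex_and_relatedness")
#' host_state_key(h, observer_lineage = 1, "none")
#' @export
host_state_key <- function(x, observer_lineage, info_level) {
  stopifnot(inherits(x, "wasp_host"))
  if (!x$alive) {
    stop("host is dead: not a valid oviposition target", call. = FALSE)
  }
  n <- host_egg_count(x)
  idx <- state_key_index(n, sum(x$eggs$lineage == observer_lineage),
                         sum(x$eggs$sex == "male"), info_level)
  sex_choice_keys(info_level)[idx]
}

#' Choose the sex of the next egg
#'
#' Under haplodiploidy an unmated (virgin) female cannot fertilize eggs
#' and therefore lays males with certainty. A mated female lays a male egg
#' with the probability her strategy assigns to the sensed host state.
#'
#' @param strat A [strategy()].
#' @param key Host-state key, as returned by [host_state_key()].
#' @param virgin Is the laying female unmated?
#' @param n Number of independent choices to draw.
#' @return Character vector of `"male"`/`"female"`.
#' @examples
#' set.seed(1)
#' choose_egg_sex(strategy(0.6, info_level = "none"), "empty", n = 5)
#' choose_egg_sex(strategy(0, info_level = "none"), "empty", virgin = TRUE)
#' @export
choose_egg_sex <- function(strat, key, virgin = FALSE, n = 1) {
  if (virgin) return(rep("male", n))
  p <- strat$sex_choice[[key]]
  if (is.null(p)) stop("unknown sex-choice key: ", key, call. = FALSE)
  ifelse(stats::runif(n) < p, "male", "female")
}

# Per-egg brood context and emergence counts for one host's egg list.
# is_male/lineage: one entry per egg. Returns premature flag, per-egg
# context name and per-egg emerger counts. A brood is mixed-sex if both
# sexes are present, and "related" if all its eggs share one lineage.
resolve_brood <- function(is_male, lineage, survival, host_limit) {
  n <- length(is_male)
  if (n == 0) {
    return(list(premature = FALSE, context = character(0),
                n_emerge = integer(0)))
  }
  if (n > host_limit) {
    return(list(premature = TRUE,
                context = rep(NA_character_, n), n_emerge = integer(n)))
  }
  nm <- sum(is_male)
  mixed <- nm > 0 && nm < n
  related <- length(unique(lineage)) == 1L
  context <- if (!mixed) {
    ifelse(is_male, "male_single_sex", "female_single_sex")
  } else if (related) {
    ifelse(is_male, "male_in_related_mixed", "female_in_related_mixed")
  } else {
    ifelse(is_male, "male_in_unrelated_mixed", "female_in_unrelated_mixed")
  }
  n_emerge <- integer(n)
  for (ctx in unique(context)) {
    sel <- context == ctx
    n_emerge[sel] <- sample_clone_size(sum(sel), survival[[ctx]])
  }
  list(premature = FALSE, context = context, n_emerge = n_emerge)
}

#' Resolve a host at the end of the oviposition phase
#'
#' Turns a host's egg list into emerging adults. A host holding more eggs
#' than `host_limit` dies prematurely and yields no adults. Otherwise each
#' egg proliferates into a clone whose size is drawn from the survival
#' distribution matching the egg's sex and brood context (single-sex;
#' mixed-sex with all clones sharing a lineage, where soldiers spare their
#' kin; or mixed-sex with unrelated clones, where soldiers depress male
#' emergence). Finally a fraction `in_host_mating_ratio` of the emerging
#' females mates with a uniformly chosen emerging male of the same brood
#' (if any), each male fertilizing at most `virility` females.
#'
#' @param x A [host()].
#' @param survival A [survival_distributions()].
#' @param in_host_mating_ratio Probability an emerging female mates within
#'   the brood before dispersal.
#' @param host_limit Maximum egg load a host survives.
#' @param virility Fertilization cap per emerging male.
#' @return A `"brood_outcome"` list: `host`, `premature_death`,
#'   `emerging_males`, `emerging_females`, and `emergers`, a data frame of
#'   adults with their source egg (`egg`), `clone` id, `mother_id`, `sex`
#'   and, for females, a `mated` flag.
#' @examples
#' set.seed(1)
#' h <- host(data.frame(mother_id = c(1, 2), lineage = c(1, 2),
#'                      sex = c("female", "male")))
#' out <- resolve_host(h, survival_distributions(), 1, host_limit = 3)
#' out$emerging_males + out$emerging_females
#' @export
resolve_host <- function(x, survival = survival_distributions(),
                         in_host_mating_ratio = 1, host_limit = 3,
                         virility = 1L) {
  stopifnot(inherits(x, "wasp_host"))
  is_male <- x$eggs$sex == "male"
  rb <- resolve_brood(is_male, x$eggs$lineage, survival, host_limit)
  if (rb$premature) {
    return(structure(list(
      host = host(x$eggs, alive = FALSE), premature_death = TRUE,
      emerging_males = 0L, emerging_females = 0L,
      emergers = data.frame(egg = integer(), clone = integer(),
                            mother_id = integer(), sex = character(),
                            mated = logical())
    ), class = "brood_outcome"))
  }
  egg_idx <- rep(seq_along(is_male), rb$n_emerge)
  emergers <- data.frame(
    egg = egg_idx,
    clone = egg_idx,
    mother_id = x$eggs$mother_id[egg_idx],
    sex = x$eggs$sex[egg_idx],
    mated = FALSE
  )
  fem <- which(emergers$sex == "female")
  mal <- which(emergers$sex == "male")
  if (length(fem) && length(mal) && in_host_mating_ratio > 0) {
    attempting <- fem[stats::runif(length(fem)) < in_host_mating_ratio]
    slots <- rep(mal, virility)
    k <- min(length(attempting), length(slots))
    if (k > 0) {
      emergers$mated[attempting[sample.int(length(attempting), k)]] <- TRUE
    }
  }
  structure(list(
    host = host(x$eggs, alive = FALSE), premature_death = FALSE,
    emerging_males = length(mal), emerging_females = length(fem),
    emergers = emergers
  ), class = "brood_outcome")
}
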