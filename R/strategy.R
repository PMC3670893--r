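#' Host-state keys available at an information level
#'
#' A female conditions her egg-sex choice on the state of the host she is
#' about to parasitize. What she can resolve depends on the information
#' level: with `"none"` she only distinguishes empty from parasitized
#' hosts; with `"relatedness"` she additionally senses whether prior eggs
#' are kin (all kin: `"related"`, none: `"unrelated"`, some: `"mixed"`);
#' with `"sex_and_relatedness"` she resolves the full cross of kinship and
#' the sexes already present (`"<relatedness>_<sexes>"`, e.g.
#' `"unrelated_male"`).
#'
#' @param info_level One of `"none"`, `"relatedness"`,
#'   `"sex_and_relatedness"`.
#' @return Character vector of key names; the first is always `"empty"`.
#' @examples
#' sex_choice_keys("none")
#' sex_choice_keys("sex_and_relatedness")
#' @export
sex_choice_keys <- function(info_level) {
  switch(info_level,
    none = c("empty", "parasitized"),
    relatedness = c("empty", "related", "unrelated", "mixed"),
    sex_and_relatedness = c("empty", as.vector(t(outer(
      c("related", "unrelated", "mixed"),
      c("male", "female", "mixed"), paste, sep = "_")))),
    stop("unknown info_level: ", info_level, call. = FALSE)
  )
}

#' Wasp strategy
#'
#' The heritable parameter set of a wasp lineage. Only `sex_choice` — the
#' per-host-state probability of laying a male (unfertilized) egg — evolves
#' in this model; the remaining components are life-history constants
#' shared by every lineage in a run and are carried on the strategy object
#' for convenience.
#'
#' @param sex_choice Named numeric vector of male-egg probabilities, one
#'   per key of [sex_choice_keys()] for the chosen `info_level`; a single
#'   unnamed value is recycled to all keys. All values must lie in
#'   `[0, 1]`.
#' @param egg_count_influence Drop in host attractiveness per egg already
#'   laid in it (see [attractiveness()]); non-negative.
#' @param in_host_mating_ratio Probability that an emerging female mates
#'   with a brood-mate male (if any emerged) before dispersal, in `[0, 1]`.
#' @param dispersal_mating Do wasps also mate after dispersal? Under a
#'   strict before-dispersal mating structure (`FALSE`, with
#'   `in_host_mating_ratio = 1`) females that emerge without brood males
#'   remain virgin and can only produce sons — the engine of the
#'   mating-structure effects across scenarios. `TRUE` with
#'   `in_host_mating_ratio = 0` models mating after dispersal only.
#' @param strategy_inheritance Weight `w` of the father's strategy in a
#'   daughter's: daughters get `w * father + (1 - w) * mother`
#'   componentwise; sons, being haploid, copy the mother exactly.
#' @param virility Number of females a mated female's son can fertilize.
#'   Small values make male mating capacity a limiting resource: when
#'   adult males are scarce (e.g. killed by soldiers in superparasitized
#'   hosts) some females stay virgin and are forced to lay male eggs,
#'   the feedback through which developmental asymmetry shapes the
#'   realized sex ratio.
#' @param virgin_son_virility Number of females a virgin's son can
#'   fertilize; must not exceed `virility`.
#' @param survival A [survival_distributions()] object.
#' @param info_level Information level defining the `sex_choice` key set.
#' @return An object of class `"wasp_strategy"`.
#' @examples
#' s <- strategy(sex_choice = 0.4, info_level = "none")
#' s$sex_choice
#' @export
strategy <- function(sex_choice = 0.5,
                     egg_count_influence = 0.3,
                     in_host_mating_ratio = 1,
                     dispersal_mating = TRUE,
                     strategy_inheritance = 0.5,
                     virility = 1L,
                     virgin_son_virility = 1L,
                     survival = survival_distributions(),
                     info_level = "sex_and_relatedness") {
  keys <- sex_choice_keys(info_level)
  if (is.null(names(sex_choice))) {
    if (length(sex_choice) == 1) {
      sex_choice <- stats::setNames(rep(as.numeric(sex_choice), length(keys)),
                                    keys)
    } else if (length(sex_choice) == length(keys)) {
      sex_choice <- stats::setNames(as.numeric(sex_choice), keys)
    } else {
      stop("sex_choice must be length 1 or one value per key (",
           length(keys), " for info_level '", info_level, "')",
           call. = FALSE)
    }
  } else {
    if (!setequal(names(sex_choice), keys)) {
      stop("sex_choice names must be exactly: ", paste(keys, collapse = ", "),
           call. = FALSE)
    }
    sex_choice <- as.numeric(sex_choice[keys]) |> stats::setNames(keys)
  }
  s <- structure(list(
    sex_choice = sex_choice,
    egg_count_influence = as.numeric(egg_count_influence),
    in_host_mating_ratio = as.numeric(in_host_mating_ratio),
    dispersal_mating = isTRUE(dispersal_mating),
    strategy_inheritance = as.numeric(strategy_inheritance),
    virility = as.integer(virility),
    virgin_son_virility = as.integer(virgin_son_virility),
    survival = survival,
    info_level = info_level
  ), class = "wasp_strategy")
  validate_strategy(s)
  s
}

validate_strategy <- function(s) {
  if (any(is.na(s$sex_choice)) || any(s$sex_choice < 0) ||
      any(s$sex_choice > 1)) {
    stop("all sex_choice probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.na(s$egg_count_influence) || s$egg_count_influence < 0) {
    stop("egg_count_influence must be >= 0", call. = FALSE)
  }
  if (s$in_host_mating_ratio < 0 || s$in_host_mating_ratio > 1) {
    stop("in_host_mating_ratio must lie in [0, 1]", call. = FALSE)
  }
  if (s$strategy_inheritance < 0 || s$strategy_inheritance > 1) {
    stop("strategy_inheritance must lie in [0, 1]", call. = FALSE)
  }
  if (s$virility < 0 || s$virgin_son_virility < 0) {
    stop("virility values must be non-negative", call. = FALSE)
  }
  if (s$virgin_son_virility > s$virility) {
    stop("virgin_son_virility must not exceed virility ",
         "(sons of virgins have lower virility)", call. = FALSE)
  }
  if (!inherits(s$survival, "survival_distributions")) {
    stop("survival must be a survival_distributions() object", call. = FALSE)
  }
  invisible(s)
}

#' @export
print.wasp_strategy <- function(x, ...) {
  cat("<wasp_strategy> info_level =", x$info_level, "\n sex_choice:\n")
  print(round(x$sex_choice, 3))
  cat(sprintf(
    " egg_count_influence = %g, in_host_mating_ratio = %g, %s,\n",
    x$egg_count_influence, x$in_host_mating_ratio,
    if (x$dispersal_mating) "dispersal mating" else "brood mating only"))
  cat(sprintf(
    " strategy_inheritance = %g, virility = %d, virgin_son_virility = %d\n",
    x$strategy_inheritance, x$virility, x$virgin_son_virility))
  invisible(x)
}

#' Draw a random sex-allocation strategy
#'
#' Returns a copy of `template` whose `sex_choice` probabilities are
#' replaced by independent uniform draws on `[0, 1]`, one per host-state
#' key. This is how candidate strategies enter the evolutionary
#' [tournament()]; every other component is copied unchanged from the
#' template, since only sex allocation evolves.
#'
#' @param template A [strategy()] supplying the non-evolving fields.
#' @return A `"wasp_strategy"` with freshly randomized `sex_choice`.
#' @examples
#' set.seed(1)
#' make_random_strategy(strategy(info_level = "none"))$sex_choice
#' @export
make_random_strategy <- function(template = strategy()) {
  validate_strategy(template)
  template$sex_choice[] <- stats::runif(length(template$sex_choice))
  template
}

#' Blend parental strategies for a daughter
#'
#' Daughters (diploid) receive a componentwise convex combination of their
#' parents' sex-choice probabilities, `w * father + (1 - w) * mother`.
#' Sons (haploid, no father) copy the mother's strategy exactly; pass
#' `sex = "male"` for that case. There is no mutation, so every offspring
#' value stays inside the closed interval spanned by its parents.
#'
#' @param mother,father [strategy()] objects with matching key sets.
#' @param w Father's weight (the "strategy inheritance" parameter), in
#'   `[0, 1]`.
#' @param sex `"female"` (blend) or `"male"` (copy of mother).
#' @return A `"wasp_strategy"` for the offspring.
#' @examples
#' m <- strategy(0.2, info_level = "none")
#' f <- strategy(0.8, info_level = "none")
#' inherit_strategy(m, f, w = 0.5)$sex_choice
#' @export
inherit_strategy <- function(mother, father, w = mother$strategy_inheritance,
                             sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (sex == "male") return(mother)
  if (w < 0 || w > 1) stop("inheritance weight w must lie in [0, 1]",
                           call. = FALSE)
  if (!identical(names(mother$sex_choice), names(father$sex_choice))) {
    stop("parent strategies have different key sets", call. = FALSE)
  }
  child <- mother
  child$sex_choice <- w * father$sex_choice + (1 - w) * mother$sex_choice
  child
}

#' Sample the number of adults emerging from one egg
#'
#' Clone sizes are normal deviates truncated below at zero (negative draws
#' are censored to 0) and rounded to the nearest integer. With `sd = 0`
#' the draw is deterministic: `round(mean)`.
#'
#' @param n Number of draws.
#' @param mean,sd Clone-size distribution parameters (adults per clone),
#'   both non-negative. A `c(mean, sd)` pair from
#'   [survival_distributions()] can be passed as `mean` with `sd` missing.
#' @return Integer vector of length `n`, all values `>= 0`.
#' @examples
#' set.seed(1)
#' mean(sample_clone_size(1e4, 45.7, 10.9))
#' sample_clone_size(3, 45.7, 0)
#' @export
sample_clone_size <- function(n, mean, sd) {
  if (missing(sd) && length(mean) == 2) {
    sd <- mean[[2]]
    mean <- mean[[1]]
  }
  if (mean < 0 || sd < 0) stop("mean and sd must be >= 0", call. = FALSE)
  as.integer(round(pmax(0, stats::rnorm(n, mean, sd))))
}
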