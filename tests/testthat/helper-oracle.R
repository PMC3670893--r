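# Independent reference implementation of one generation, written
# straight from the model rules with plain data frames, for degenerate
# configurations where every outcome is forced: sd = 0 survival,
# sex-choice probabilities in {0, 1}, in-host mating ratio in {0, 1} and
# a fixed host-presentation schedule. Used to check step_generation()
# exactly, and deliberately independent of the package's engine.

# females: data.frame(lineage, mated, male_p) — male_p in {0,1} is the
# probability of a male egg for every host state (flat strategies keep
# the oracle's sex choice state-free and deterministic).
oracle_generation <- function(females, config, template, presentation) {
  n_f <- nrow(females)
  thr <- config$host_acceptance_threshold
  inf <- template$egg_count_influence
  eggs <- data.frame(host = integer(), mother = integer(),
                     lineage = integer(), male = logical())
  for (t in seq_len(config$lifespan)) {
    for (i in seq_len(n_f)) {
      h <- presentation[i, t]
      n_in <- sum(eggs$host == h)
      if (max(0, 1 - inf * n_in) > thr) {
        male <- if (!females$mated[i]) TRUE else females$male_p[i] == 1
        eggs <- rbind(eggs, data.frame(host = h, mother = i,
                                       lineage = females$lineage[i],
                                       male = male))
      }
    }
  }
  surv_mean <- function(ctx) template$survival[[ctx]][["mean"]]
  premature <- 0L
  clone_f <- integer(0)   # per female egg, in laying order
  clone_m <- integer(0)
  fem_hosts <- integer(0) # host of each emerging-female clone
  mal_hosts <- integer(0)
  mal_vson <- logical(0)  # male clone laid by a virgin mother?
  for (h in unique(eggs$host)) {
    eh <- eggs[eggs$host == h, , drop = FALSE]
    if (nrow(eh) > config$host_limit) {
      premature <- premature + 1L
      next
    }
    mixed <- any(eh$male) && any(!eh$male)
    related <- length(unique(eh$lineage)) == 1L
    for (j in seq_len(nrow(eh))) {
      ctx <- if (!mixed) {
        if (eh$male[j]) "male_single_sex" else "female_single_sex"
      } else if (related) {
        if (eh$male[j]) "male_in_related_mixed" else "female_in_related_mixed"
      } else {
        if (eh$male[j]) "male_in_unrelated_mixed" else
          "female_in_unrelated_mixed"
      }
      size <- as.integer(round(max(0, surv_mean(ctx))))
      if (eh$male[j]) {
        clone_m <- c(clone_m, size)
        mal_hosts <- c(mal_hosts, h)
        mal_vson <- c(mal_vson, !females$mated[eh$mother[j]])
      } else {
        clone_f <- c(clone_f, size)
        fem_hosts <- c(fem_hosts, h)
      }
    }
  }
  adults_f <- sum(clone_f)
  adults_m <- sum(clone_m)
  # in-host mating (all-or-none ratio), then optional dispersal mating;
  # a male's fertilization cap depends on whether his mother was virgin
  clone_cap <- clone_m * ifelse(mal_vson, template$virgin_son_virility,
                                template$virility)
  mated <- 0L
  cap_left <- 0L
  if (template$in_host_mating_ratio >= 1) {
    for (h in unique(c(fem_hosts, mal_hosts))) {
      nf <- sum(clone_f[fem_hosts == h])
      cap_h <- sum(clone_cap[mal_hosts == h])
      k <- min(nf, cap_h)
      mated <- mated + k
      cap_left <- cap_left + cap_h - k
    }
  } else {
    cap_left <- sum(clone_cap)
  }
  if (template$dispersal_mating) {
    mated <- mated + min(adults_f - mated, cap_left)
  }
  list(
    eggs_male = sum(eggs$male), eggs_female = sum(!eggs$male),
    premature = premature,
    adults_male = adults_m, adults_female = adults_f,
    n_mated = mated,
    female_clones = sort(clone_f), male_clones = sort(clone_m)
  )
}

# Build a wasp_population for hand-specified females (flat strategies).
# male_p per female in {0,1}; mated females count as fertilized by a
# male of their own strategy.
oracle_population <- function(females, config, template) {
  keys <- polywasp::sex_choice_keys(config$info_level)
  n <- nrow(females)
  strat <- matrix(females$male_p, n, length(keys),
                  dimnames = list(NULL, keys))
  anc <- matrix(1, n, 1)
  mate <- strat
  mate[!females$mated, ] <- NA_real_
  mate_anc <- matrix(ifelse(females$mated, 1, NA_real_), n, 1)
  m0 <- matrix(numeric(0), 0, length(keys), dimnames = list(NULL, keys))
  polywasp:::new_population(
    keys,
    strat, females$mated, mate, mate_anc,
    as.integer(females$lineage), anc,
    m0, integer(0), matrix(numeric(0), 0, 1), logical(0), integer(0)
  )
}

# Summarize a step_generation() result in the oracle's terms.
engine_summary <- function(out) {
  pop <- out$population
  list(
    eggs_male = out$stats$eggs_male, eggs_female = out$stats$eggs_female,
    premature = out$stats$premature_host_deaths,
    adults_male = out$stats$adults_male,
    adults_female = out$stats$adults_female,
    n_mated = sum(pop$females$mated),
    female_clones = sort(as.integer(table(pop$females$lineage))),
    male_clones = sort(as.integer(table(pop$males$lineage)))
  )
}

# Degenerate configurations shared by the oracle unit test and the
# acceptance suite: each case fully determined given its presentation.
oracle_cases <- function() {
  surv0 <- survival_distributions(
    female_single_sex = c(45.7, 0), male_single_sex = c(32.4, 0),
    female_in_unrelated_mixed = c(40, 0), male_in_unrelated_mixed = c(20, 0)
  )
  cfg <- function(...) simulation_config(host_count = 5L, host_limit = 3L,
                                         generations = 1L, lifespan = 2L,
                                         ...)
  tpl <- function(...) strategy(survival = surv0, ...)
  list(
    single_mother_daughters_only = list(
      config = cfg(host_acceptance_threshold = 0.99),
      template = tpl(sex_choice = 0, egg_count_influence = 0.3),
      females = data.frame(lineage = 1L, mated = TRUE, male_p = 0),
      presentation = matrix(c(1L, 2L), 1, 2)
    ),
    unrelated_mixed_brood = list(
      config = cfg(host_acceptance_threshold = 0.2),
      template = tpl(sex_choice = 0, egg_count_influence = 0.3,
                     virility = 1L),
      # mated mother lays females; virgin lays males; both visit host 1
      # then host 2 -> two unrelated mixed broods
      females = data.frame(lineage = c(1L, 2L), mated = c(TRUE, FALSE),
                           male_p = c(0, 1)),
      presentation = matrix(c(1L, 1L, 2L, 2L), 2, 2)
    ),
    overcrowded_host_dies = list(
      config = cfg(host_acceptance_threshold = 0.05),
      template = tpl(sex_choice = 0, egg_count_influence = 0.2),
      # 3 mothers x 2 visits to the same host = 6 eggs > limit
      females = data.frame(lineage = 1:3, mated = TRUE, male_p = c(0, 0, 0)),
      presentation = matrix(1L, 3, 2)
    ),
    postmating_structure = list(
      config = cfg(host_acceptance_threshold = 0.2),
      template = tpl(sex_choice = 0, egg_count_influence = 0.3,
                     in_host_mating_ratio = 0, virility = 2L),
      females = data.frame(lineage = c(1L, 2L), mated = c(TRUE, FALSE),
                           male_p = c(0, 1)),
      presentation = matrix(c(1L, 1L, 2L, 2L), 2, 2)
    ),
    all_male_lineage = list(
      config = cfg(host_acceptance_threshold = 0.5),
      template = tpl(sex_choice = 1, egg_count_influence = 0.3),
      females = data.frame(lineage = c(1L, 2L), mated = c(TRUE, TRUE),
                           male_p = c(1, 1)),
      presentation = matrix(c(1L, 2L, 3L, 4L), 2, 2)
    )
  )
}
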