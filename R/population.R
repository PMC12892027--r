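#' Configuration for a synthetic study population
#'
#' Describes a city population containing a hidden, networked subpopulation
#' of eligible ENDS (electronic nicotine delivery system) users. Only
#' eligible-eligible social ties are modelled, since only those carry
#' chain-referral recruitment.
#'
#' @param n_total Total population size (eligible + ineligible).
#' @param prevalence_eligible Fraction of the population eligible
#'   (used ENDS in past 12 months, aged >= 15, resident). Must be in (0, 1).
#' @param mean_degree Target mean of the realized eligible-alter degree
#'   distribution.
#' @param degree_dispersion Negative-binomial `size` (dispersion) parameter;
#'   smaller values give a heavier right tail.
#' @param degree_max Upper truncation for degrees (default 99, the largest
#'   network size the instrument accepts).
#' @param homophily Named numeric vector of per-trait assortativity strengths
#'   in `[0, 1]`, e.g. `c(zone = 0.4)`. 0 means proportionate mixing.
#' @param trait_marginals Named list of per-trait category probability
#'   vectors. Defaults emulate the demographic shape of an urban ENDS-user
#'   sample: `age_group` (15-24, 25-34, 35+), `sex`, `zone`.
#' @param rng_seed Integer seed; the same seed reproduces the population
#'   byte for byte.
#' @return A `webrds_pop_config` list.
#' @export
population_config <- function(n_total,
                              prevalence_eligible,
                              mean_degree,
                              degree_dispersion = 1.5,
                              degree_max = 99,
                              homophily = c(zone = 0),
                              trait_marginals = NULL,
                              rng_seed = 1L) {
  if (!is.numeric(n_total) || n_total < 1) abort("`n_total` must be a positive integer.")
  if (!is.numeric(prevalence_eligible) ||
      prevalence_eligible <= 0 || prevalence_eligible >= 1) {
    abort("`prevalence_eligible` must lie strictly inside (0, 1).")
  }
  if (n_total * prevalence_eligible < 2) {
    abort("Expected fewer than 2 eligible members: no network is possible.")
  }
  if (mean_degree <= 0) abort("`mean_degree` must be positive.")
  if (degree_max < 1) abort("`degree_max` must be >= 1.")
  if (mean_degree >= degree_max) abort("`mean_degree` must be below `degree_max`.")
  if (length(homophily) && (any(homophily < 0) | any(homophily > 1))) {
    abort("`homophily` coefficients must lie in [0, 1].")
  }
  marg <- trait_marginals %||% list(
    age_group = c(`15-24` = 0.38, `25-34` = 0.42, `35+` = 0.20),
    sex       = c(female = 0.44, male = 0.56),
    zone      = c(south = 0.35, north = 0.35, west = 0.15, center = 0.15)
  )
  for (nm in names(marg)) {
    if (abs(sum(marg[[nm]]) - 1) > 1e-9) {
      abort(paste0("trait_marginals$", nm, " must sum to 1."))
    }
  }
  if (length(homophily) && !all(names(homophily) %in% names(marg))) {
    abort("every `homophily` name must match a trait in `trait_marginals`.")
  }
  structure(
    list(
      n_total = as.integer(n_total),
      prevalence_eligible = prevalence_eligible,
      mean_degree = mean_degree,
      degree_dispersion = degree_dispersion,
      degree_max = as.integer(degree_max),
      homophily = homophily,
      trait_marginals = marg,
      rng_seed = as.integer(rng_seed)
    ),
    class = "webrds_pop_config"
  )
}

# Mean of a negative binomial truncated to [1, kmax], as a function of mu.
trunc_nbinom_mean <- function(mu, size, kmax) {
  k <- 1:kmax
  p <- dnbinom(k, mu = mu, size = size)
  sum(k * p) / sum(p)
}

# Calibrate mu so the truncated mean equals the target, then sample.
sample_trunc_nbinom <- function(n, target_mean, size, kmax) {
  f <- function(mu) trunc_nbinom_mean(mu, size, kmax) - target_mean
  lo <- 1e-3
  if (f(lo) > 0) {
    mu <- lo # target below the truncation floor's reach; smallest mu
  } else {
    mu <- uniroot(f, c(lo, kmax), tol = 1e-8)$root
  }
  out <- integer(0)
  while (length(out) < n) {
    draw <- rnbinom(2L * (n - length(out)) + 10L, mu = mu, size = size)
    draw <- draw[draw >= 1 & draw <= kmax]
    out <- c(out, draw)
  }
  out[seq_len(n)]
}

# Name pools for synthetic email addresses ("first.last@example.test",
# optionally with a middle letter token to keep normalized forms unique).
.first_names <- c(
  "ana", "bruno", "carla", "diego", "elisa", "fabio", "gabriela", "heitor",
  "isabela", "joao", "karina", "lucas", "mariana", "nelson", "olivia",
  "paulo", "quiteria", "rafael", "sofia", "thiago", "ursula", "vitor",
  "wagner", "ximena", "yara", "zeca", "beatriz", "caio", "daniela", "edson"
)
.last_names <- c(
  "silva", "santos", "oliveira", "souza", "lima", "pereira", "costa",
  "ferreira", "rodrigues", "almeida", "nascimento", "carvalho", "araujo",
  "ribeiro", "gomes", "martins", "rocha", "barbosa", "alves", "monteiro",
  "cardoso", "teixeira", "moreira", "correia", "cavalcanti", "dias",
  "castro", "campos", "duarte", "farias"
)

# n unique synthetic emails whose *normalized* forms are also unique.
synth_emails <- function(n) {
  base <- expand.grid(f = .first_names, l = .last_names,
                      stringsAsFactors = FALSE)
  keys <- paste(base$f, base$l, sep = ".")
  if (n > length(keys) * 27) abort("email name pool exhausted")
  out <- character(n)
  k <- length(keys)
  for (i in seq_len(n)) {
    j <- ((i - 1) %% k) + 1
    rep_i <- (i - 1) %/% k
    mid <- if (rep_i == 0) "" else paste0(".", letters[rep_i])
    out[i] <- paste0(base$f[j], mid, ".", base$l[j], "@example.test")
  }
  out
}

# Dates of birth consistent with an age-group label at a fixed reference
# date, pairwise distinct and — when the age band has room — at least 2 days
# apart (drawn on a 2-day grid). This separability, under which no two
# people share or nearly share a date of birth, is an idealization of the
# intake system's identity assumption (see the methods vignette): the
# exact-DOB block and the +/-1-day proximity heuristic are then pure fraud
# signals. Very large populations overflow the 2-day grid and degrade to
# plain uniqueness for the crowded band.
synth_dobs <- function(age_group, ref_date = as.Date("2022-08-01")) {
  rng <- list(
    `15-24` = c(15, 24), `25-34` = c(25, 34), `35+` = c(35, 60)
  )
  n <- length(age_group)
  band_n <- table(age_group)
  spacing <- lapply(rng, function(b) 2L)
  for (bn in names(band_n)) {
    b <- rng[[bn]]
    days <- (b[2] + 1 - b[1]) * 365.25 - 6
    if (band_n[[bn]] > 0.7 * days / 2) spacing[[bn]] <- 1L
    if (band_n[[bn]] > 0.8 * days) spacing[[bn]] <- 0L # band saturated
  }
  out <- rep(ref_date, n)
  taken <- new.env(hash = TRUE)
  for (i in seq_len(n)) {
    bn <- as.character(age_group[i])
    b <- rng[[bn]]
    sp <- spacing[[bn]]
    if (sp == 0L) {
      out[i] <- ref_date - round(runif(1, b[1] * 365.25 + 3,
                                       (b[2] + 1) * 365.25 - 3))
      next
    }
    repeat {
      age_days <- sp * round(runif(1, (b[1] * 365.25 + 3) / sp,
                                   ((b[2] + 1) * 365.25 - 3) / sp))
      d <- ref_date - age_days
      key <- as.character(d)
      if (is.null(taken[[key]])) {
        assign(key, TRUE, envir = taken)
        out[i] <- d
        break
      }
    }
  }
  out
}

# Trait-biased double-edge swaps pushing the within-group edge fraction of
# `trait` towards base + h * (1 - base), where base is the proportionate-
# mixing expectation sum(p_c^2).
rewire_homophily <- function(edges, trait, h) {
  if (h <= 0 || nrow(edges) < 2) return(edges)
  p <- table(trait) / length(trait)
  base <- sum(p^2)
  target <- base + h * (1 - base)
  a <- edges[, 1]; b <- edges[, 2]
  within <- trait[a] == trait[b]
  m <- length(a)
  ekey <- function(x, y) paste(pmin(x, y), pmax(x, y))
  eset <- new.env(hash = TRUE)
  for (i in seq_len(m)) assign(ekey(a[i], b[i]), TRUE, envir = eset)
  max_iter <- 40L * m
  it <- 0L
  while (mean(within) < target && it < max_iter) {
    it <- it + 1L
    ij <- sample.int(m, 2L)
    i <- ij[1]; j <- ij[2]
    # propose (a_i-b_j), (a_j-b_i)
    na1 <- a[i]; nb1 <- b[j]; na2 <- a[j]; nb2 <- b[i]
    if (na1 == nb1 || na2 == nb2) next
    gain <- (trait[na1] == trait[nb1]) + (trait[na2] == trait[nb2]) -
      within[i] - within[j]
    if (gain <= 0) next
    k1 <- ekey(na1, nb1); k2 <- ekey(na2, nb2)
    if (!is.null(eset[[k1]]) || !is.null(eset[[k2]]) || k1 == k2) next
    rm(list = c(ekey(a[i], b[i]), ekey(a[j], b[j])), envir = eset)
    assign(k1, TRUE, envir = eset)
    assign(k2, TRUE, envir = eset)
    b[i] <- nb1; a[j] <- na2; b[j] <- nb2
    within[i] <- trait[a[i]] == trait[b[i]]
    within[j] <- trait[a[j]] == trait[b[j]]
  }
  cbind(a, b)
}

#' Generate a synthetic population with a hidden eligible subnetwork
#'
#' Draws eligibility, demographic traits, device history, unique synthetic
#' emails and dates of birth for every person, then connects the eligible
#' members by a simple undirected graph: degrees are sampled from a negative
#' binomial truncated to `[1, degree_max]` (truncated mean calibrated to
#' `mean_degree`), wired by a configuration model, simplified, and optionally
#' rewired towards per-trait homophily targets. `true_degree` is each node's
#' realized number of eligible alters.
#'
#' @param config A [population_config()].
#' @return A `webrds_population`: list with `nodes` (one row per person) and
#'   `edges` (eligible-eligible ties, `from`/`to` person ids).
#' @examples
#' pop <- generate_population(population_config(500, 0.2, 5, rng_seed = 1))
#' mean(pop$nodes$true_degree[pop$nodes$eligible])
#' @export
generate_population <- function(config) {
  if (!inherits(config, "webrds_pop_config")) {
    abort("`config` must come from population_config().")
  }
  withr::with_seed(config$rng_seed, {
    n <- config$n_total
    eligible <- runif(n) < config$prevalence_eligible
    if (sum(eligible) < 2) {
      abort("Fewer than 2 eligible members were realized: no network is possible.")
    }
    marg <- config$trait_marginals
    nodes <- tibble(
      person_id = sprintf("P%05d", seq_len(n)),
      eligible = eligible
    )
    for (tr in names(marg)) {
      nodes[[tr]] <- sample(names(marg[[tr]]), n, replace = TRUE,
                            prob = marg[[tr]])
    }
    nodes$ever_cigarette <- runif(n) < ifelse(eligible, 0.81, 0.50)
    # device history: nonempty iff eligible (e-cig dominant, per field surveys)
    nodes$device_ecig <- eligible & (runif(n) < 0.95)
    nodes$device_htp  <- eligible & (runif(n) < 0.34)
    nodes$device_vape <- eligible & (runif(n) < 0.33)
    none <- eligible & !(nodes$device_ecig | nodes$device_htp | nodes$device_vape)
    nodes$device_ecig[none] <- TRUE
    nodes$email <- synth_emails(n)
    nodes$dob <- synth_dobs(nodes$age_group)

    elig_idx <- which(eligible)
    m <- length(elig_idx)
    degs <- sample_trunc_nbinom(m, config$mean_degree,
                                config$degree_dispersion, config$degree_max)
    degs <- pmin(degs, m - 1L)
    if (sum(degs) %% 2 == 1) degs[which.max(degs)] <- degs[which.max(degs)] - 1L
    g <- igraph::sample_degseq(degs, method = "configuration")
    g <- igraph::simplify(g)
    em <- igraph::as_edgelist(g, names = FALSE)
    # homophily rewiring, one trait at a time
    hp <- config$homophily
    for (tr in names(hp)) {
      em <- rewire_homophily(em, nodes[[tr]][elig_idx], hp[[tr]])
    }
    deg_realized <- tabulate(c(em[, 1], em[, 2]), nbins = m)
    nodes$true_degree <- 0L
    nodes$true_degree[elig_idx] <- as.integer(deg_realized)
    edges <- tibble(
      from = nodes$person_id[elig_idx[em[, 1]]],
      to   = nodes$person_id[elig_idx[em[, 2]]]
    )
    structure(list(nodes = nodes, edges = edges, config = config),
              class = "webrds_population")
  })
}

#' @export
print.webrds_population <- function(x, ...) {
  cat("<webrds_population>\n")
  cat("  persons:", nrow(x$nodes),
      " eligible:", sum(x$nodes$eligible),
      " ties:", nrow(x$edges), "\n")
  cat("  mean eligible degree:",
      round(mean(x$nodes$true_degree[x$nodes$eligible]), 2), "\n")
  invisible(x)
}

#' Apply respondent degree heaping
#'
#' Self-reported network sizes above 5 tend to be rounded to the nearest
#' multiple of 5; sizes of 5 or fewer are reported exactly. Reported values
#' are capped at `degree_max`.
#'
#' @param true_degree Integer vector of true degrees (>= 0).
#' @param heap_prob Probability that a degree above 5 is heaped.
#' @param degree_max Reporting cap (default 99).
#' @return Integer vector of reported degrees.
#' @examples
#' apply_degree_heaping(c(3, 12, 250), heap_prob = 1)
#' @export
apply_degree_heaping <- function(true_degree, heap_prob = 0.5, degree_max = 99) {
  if (any(true_degree < 0)) abort("`true_degree` must be nonnegative.")
  assert_prob(heap_prob, "heap_prob")
  d <- as.numeric(true_degree)
  heap <- d > 5 & runif(length(d)) < heap_prob
  d[heap] <- 5 * round_half_up(d[heap] / 5)
  as.integer(pmax(0, pmin(d, degree_max)))
}

#' Attach a degree-linked binary trait to a population
#'
#' Adds a logical column whose prevalence is calibrated to `prevalence`
#' overall while the log-odds increase with log degree, producing the
#' degree-trait correlation under which unweighted sample proportions are
#' biased and reciprocal-degree weighting should help.
#'
#' @param population A `webrds_population`.
#' @param name Column name for the trait.
#' @param prevalence Target overall prevalence among eligible members.
#' @param strength Logistic slope on standardized log(degree + 1).
#' @return The population with the trait column added to `nodes` (FALSE for
#'   ineligible members).
#' @export
add_degree_linked_trait <- function(population, name = "trait",
                                    prevalence = 0.3, strength = 1) {
  nodes <- population$nodes
  el <- nodes$eligible
  z <- scale(log(nodes$true_degree[el] + 1))[, 1]
  f <- function(a) mean(stats::plogis(a + strength * z)) - prevalence
  a <- uniroot(f, c(-20, 20))$root
  p <- stats::plogis(a + strength * z)
  tr <- rep(FALSE, nrow(nodes))
  tr[el] <- runif(sum(el)) < p
  nodes[[name]] <- tr
  population$nodes <- nodes
  population
}
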