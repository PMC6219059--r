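#' Simulation configuration
#'
#' Bundles the parameters of the stochastic population simulator. Defaults
#' describe the reference study conditions used throughout the package tests:
#' an unselected two-generation design with 25 sires and 250 dams, two
#' offspring per dam (500 phenotyped animals in the final cohort), an
#' infinitesimal additive trait with heritability 0.4
#' (`sigma2_u = 0.4`, `sigma2_e = 0.6`), and 25 contemporary groups with
#' effect standard deviation 1 (comparable to the phenotypic SD).
#'
#' @param n_sires,n_dams Number of sires and dams used as parents per
#'   generation.
#' @param offspring_per_mating Offspring per dam (each dam is mated to one
#'   randomly drawn sire).
#' @param n_generations Number of offspring generations below the founders.
#' @param sigma2_u,sigma2_e Additive genetic and residual variances.
#' @param n_groups Number of contemporary-group levels per phenotyped
#'   generation.
#' @param sd_group Standard deviation of the Gaussian contemporary-group
#'   effects.
#' @param n_loci Number of unlinked biallelic marker loci to gene-drop
#'   (0 = no genotypes).
#' @param founder_freqs Optional vector of founder allele frequencies
#'   (length `n_loci`); default drawn uniformly in (0.05, 0.95).
#' @param selection Parent-selection rule between generations: `"none"`
#'   (random), `"phenotype"`, `"tbv"` or `"ebv"` (truncation on the
#'   criterion, within sex).
#' @param phenotyped Which generations appear in the returned phenotype
#'   table: `"last"` (final cohort only, the default) or `"all"`.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_sires = 25, n_dams = 250, offspring_per_mating = 2,
                       n_generations = 1, sigma2_u = 0.4, sigma2_e = 0.6,
                       n_groups = 25, sd_group = 1, n_loci = 0,
                       founder_freqs = NULL,
                       selection = c("none", "phenotype", "tbv", "ebv"),
                       phenotyped = c("last", "all")) {
  selection <- match.arg(selection)
  phenotyped <- match.arg(phenotyped)
  stopifnot(n_sires >= 1, n_dams >= 1, offspring_per_mating >= 1,
            n_generations >= 0, sigma2_u > 0, sigma2_e > 0,
            n_groups >= 1, sd_group >= 0, n_loci >= 0)
  structure(list(
    n_sires = n_sires, n_dams = n_dams,
    offspring_per_mating = offspring_per_mating,
    n_generations = n_generations,
    sigma2_u = sigma2_u, sigma2_e = sigma2_e,
    n_groups = n_groups, sd_group = sd_group,
    n_loci = n_loci, founder_freqs = founder_freqs,
    selection = selection, phenotyped = phenotyped
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d sires x %d dams, %d offspring/mating, %d generation(s), h2 = %.2f, %d groups (sd %.2f), selection = %s\n",
    x$n_sires, x$n_dams, x$offspring_per_mating, x$n_generations,
    x$sigma2_u / (x$sigma2_u + x$sigma2_e), x$n_groups, x$sd_group,
    x$selection))
  invisible(x)
}

#' Simulate a multi-generation pedigree (random mating)
#'
#' Discrete non-overlapping generations: founders (generation 0) are
#' `n_sires` males and `n_dams` females; in each later generation every dam
#' is mated to one randomly drawn sire and produces
#' `offspring_per_mating` offspring of random sex. Parents of generation
#' `g + 1` are drawn at random from generation `g` (use
#' [simulate_population()] for truncation selection).
#'
#' @param config A [sim_config()].
#' @return A [as_pedigree()] tibble with columns `id`, `sire`, `dam`,
#'   `generation`, `sex`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ped <- founder_rows(config)
  for (g in seq_len(config$n_generations)) {
    parents <- draw_parents(ped[ped$generation == g - 1, ], config,
                            criterion = NULL)
    ped <- dplyr::bind_rows(ped, mate(parents, g, config))
  }
  as_pedigree(ped)
}

founder_rows <- function(config) {
  tibble::tibble(
    id = c(sprintf("S%03d", seq_len(config$n_sires)),
           sprintf("D%04d", seq_len(config$n_dams))),
    sire = NA_character_, dam = NA_character_,
    generation = 0L,
    sex = c(rep("M", config$n_sires), rep("F", config$n_dams))
  )
}

draw_parents <- function(candidates, config, criterion = NULL) {
  pick <- function(rows, n, sex) {
    if (nrow(rows) < n) {
      stop("infeasible family structure: ", n, " ", sex,
           " parents demanded but only ", nrow(rows), " available",
           call. = FALSE)
    }
    if (n < 1) stop("selection leaves fewer than one ", sex, " parent",
                    call. = FALSE)
    if (is.null(criterion)) {
      rows[sample.int(nrow(rows), n), ]
    } else {
      truncation_select(rows, criterion, n / nrow(rows))
    }
  }
  list(sires = pick(candidates[candidates$sex == "M", ], config$n_sires, "male"),
       dams = pick(candidates[candidates$sex == "F", ], config$n_dams, "female"))
}

mate <- function(parents, g, config) {
  n_off <- config$n_dams * config$offspring_per_mating
  dam_id <- rep(parents$dams$id, each = config$offspring_per_mating)
  sire_of_dam <- sample(parents$sires$id, config$n_dams, replace = TRUE)
  tibble::tibble(
    id = sprintf("G%d_%04d", g, seq_len(n_off)),
    sire = rep(sire_of_dam, each = config$offspring_per_mating),
    dam = dam_id,
    generation = as.integer(g),
    # balanced sex ratio in random order keeps multi-generation designs
    # feasible with exact parent counts
    sex = sample(rep_len(c("M", "F"), n_off))
  )
}

#' Simulate true breeding values down a pedigree
#'
#' Infinitesimal model: founders are drawn `N(0, sigma2_u)`; each offspring
#' is the parent average plus a Mendelian-sampling deviation with variance
#' `sigma2_u * (1 - 0.25 (1 + F_s) - 0.25 (1 + F_d))` (terms dropped for
#' unknown parents), so that `Var(u) = A sigma2_u` exactly.
#'
#' @param pedigree A [as_pedigree()] object.
#' @param sigma2_u Additive genetic variance.
#' @param F Optional precomputed inbreeding coefficients in pedigree order
#'   (avoids an O(n^2) NRM build in replicate loops).
#' @return Named numeric vector of TBV in pedigree order.
#' @export
simulate_tbv <- function(pedigree, sigma2_u, F = NULL) {
  ped <- ensure_pedigree(pedigree)
  if (is.null(F)) F <- inbreeding(ped)$F
  n <- nrow(ped)
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  ms_var <- sigma2_u * (1 -
    ifelse(is.na(s), 0, 0.25 * (1 + F[pmax(s, 1L)])) -
    ifelse(is.na(d), 0, 0.25 * (1 + F[pmax(d, 1L)])))
  ms <- stats::rnorm(n, 0, sqrt(pmax(ms_var, 0)))
  u <- numeric(n)
  for (i in seq_len(n)) {
    pa <- 0
    if (!is.na(s[i])) pa <- pa + 0.5 * u[s[i]]
    if (!is.na(d[i])) pa <- pa + 0.5 * u[d[i]]
    u[i] <- pa + ms[i]
  }
  stats::setNames(u, ped$id)
}

#' Simulate phenotypes
#'
#' `y = beta[cg] + u + e` with `e ~ N(0, sigma2_e)` and Gaussian
#' contemporary-group effects. Groups are assigned balanced-at-random within
#' each phenotyped generation.
#'
#' @param pedigree Pedigree with a `generation` column (or any id table).
#' @param u Named TBV vector (from [simulate_tbv()]).
#' @param config A [sim_config()] supplying `sigma2_e`, `n_groups`,
#'   `sd_group` and `phenotyped`.
#' @param beta Optional named vector of contemporary-group effects to reuse
#'   across replicates (names are group labels).
#' @param generations Integer vector of generations to phenotype; defaults
#'   according to `config$phenotyped`.
#' @return Tibble with columns `id`, `y`, `cg` (factor), `generation`, and
#'   attribute `"beta"` (tibble of the group effects used).
#' @export
simulate_phenotypes <- function(pedigree, u, config, beta = NULL,
                                generations = NULL) {
  ped <- tibble::as_tibble(pedigree)
  if (!"generation" %in% names(ped)) ped$generation <- 0L
  if (is.null(generations)) {
    generations <- if (config$phenotyped == "all") unique(ped$generation)
                   else max(ped$generation)
  }
  rows <- ped[ped$generation %in% generations, ]
  out <- purrr::map_dfr(split(rows, rows$generation), function(gen_rows) {
    g <- gen_rows$generation[1]
    m <- config$n_groups
    cg <- sprintf("g%d_cg%02d", g, sample(rep_len(seq_len(m), nrow(gen_rows))))
    tibble::tibble(id = gen_rows$id, cg = cg, generation = g)
  })
  levels <- sort(unique(out$cg))
  if (is.null(beta)) {
    beta <- stats::setNames(stats::rnorm(length(levels), 0, config$sd_group),
                            levels)
  }
  out$cg <- factor(out$cg, levels = names(beta))
  out$y <- unname(beta[as.character(out$cg)]) + unname(u[out$id]) +
    stats::rnorm(nrow(out), 0, sqrt(config$sigma2_e))
  out <- dplyr::relocate(out, "id", "y", "cg", "generation")
  attr(out, "beta") <- tibble::tibble(cg = names(beta), effect = unname(beta))
  out
}

#' Truncation selection
#'
#' Retains the top fraction of rows by a criterion column (ties broken by
#' order). Errors if fewer than one row would be selected.
#'
#' @param data Candidate table.
#' @param value Name of the criterion column.
#' @param proportion Selected proportion in `(0, 1]`.
#' @return The selected rows of `data`.
#' @export
truncation_select <- function(data, value, proportion) {
  stopifnot(proportion > 0, proportion <= 1)
  n_sel <- max(round(proportion * nrow(data)), 0)
  if (n_sel < 1) {
    stop("selected proportion yields fewer than one parent", call. = FALSE)
  }
  data[order(data[[value]], decreasing = TRUE)[seq_len(n_sel)], ]
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder alleles are sampled at given frequencies; each offspring receives
#' one allele per locus from each parent at random (unlinked loci, no
#' mutation). Unknown parents contribute base-population gametes.
#'
#' @param pedigree A [as_pedigree()] object.
#' @param n_loci Number of loci.
#' @param founder_freqs Optional allele-frequency vector (default uniform in
#'   (0.05, 0.95)).
#' @return Dosage matrix (individuals x loci, values 0/1/2) with id rownames
#'   and attribute `"founder_freqs"`.
#' @export
gene_drop <- function(pedigree, n_loci, founder_freqs = NULL) {
  stopifnot(n_loci >= 1)
  ped <- ensure_pedigree(pedigree)
  n <- nrow(ped)
  if (is.null(founder_freqs)) founder_freqs <- stats::runif(n_loci, 0.05, 0.95)
  stopifnot(length(founder_freqs) == n_loci)
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  a1 <- matrix(0L, n, n_loci)
  a2 <- matrix(0L, n, n_loci)
  base_gamete <- function() {
    stats::rbinom(n_loci, 1L, founder_freqs)
  }
  gamete_from <- function(parent) {
    pick <- stats::runif(n_loci) < 0.5
    ifelse(pick, a1[parent, ], a2[parent, ])
  }
  for (i in seq_len(n)) {
    a1[i, ] <- if (is.na(s[i])) base_gamete() else gamete_from(s[i])
    a2[i, ] <- if (is.na(d[i])) base_gamete() else gamete_from(d[i])
  }
  M <- a1 + a2
  dimnames(M) <- list(ped$id, sprintf("L%05d", seq_len(n_loci)))
  attr(M, "founder_freqs") <- founder_freqs
  M
}

#' Simulate a complete population with ground truth
#'
#' Runs the generation loop: founders, true breeding values, phenotypes, and
#' (optionally) truncation selection of parents on phenotype, TBV or EBV
#' between generations. EBV selection solves the animal model on the records
#' accumulated so far using the true variance components. Records the
#' realized genetic variance per generation and the selection history.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed (recorded in the output).
#' @return An object of class `"sim_population"`: a list with `pedigree`,
#'   `truth` (tibble `id`, `u`, `generation`), `phenotypes` (as configured),
#'   `beta` (contemporary-group effects), `genotypes` (or `NULL`),
#'   `gen_var` (realized genetic variance per generation),
#'   `selection_history`, `config` and `seed`.
#' @export
simulate_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  ped <- founder_rows(config)
  u <- stats::setNames(stats::rnorm(nrow(ped), 0, sqrt(config$sigma2_u)),
                       ped$id)
  phen <- NULL
  history <- list()
  for (g in seq_len(config$n_generations)) {
    prev <- ped[ped$generation == g - 1, ]
    criterion <- NULL
    if (config$selection != "none") {
      crit_val <- switch(config$selection,
        phenotype = sim_selection_phenotype(prev, u, config),
        tbv = u[prev$id],
        ebv = sim_selection_ebv(ped, prev, u, config))
      prev$.criterion <- crit_val
      criterion <- ".criterion"
    }
    parents <- draw_parents(prev, config, criterion = criterion)
    history[[g]] <- tibble::tibble(
      generation = g, rule = config$selection,
      n_male_candidates = sum(prev$sex == "M"),
      n_female_candidates = sum(prev$sex == "F"),
      n_sires = nrow(parents$sires), n_dams = nrow(parents$dams))
    off <- mate(parents, g, config)
    ped_new <- dplyr::bind_rows(ped[names(off)], off)
    F_new <- inbreeding(as_pedigree(ped_new))$F
    u <- sim_extend_tbv(ped_new, u, F_new, config$sigma2_u)
    ped <- dplyr::bind_rows(ped, off)
  }
  ped <- as_pedigree(ped)
  phen <- simulate_phenotypes(ped, u, config)
  geno <- if (config$n_loci > 0) {
    gene_drop(ped, config$n_loci, config$founder_freqs)
  }
  gen_var <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(generation = ped$generation, u = u[ped$id]),
                    .data$generation),
    var_u = stats::var(.data$u), .groups = "drop")
  structure(list(
    pedigree = ped,
    truth = tibble::tibble(id = ped$id, u = unname(u[ped$id]),
                           generation = ped$generation),
    phenotypes = phen,
    beta = attr(phen, "beta"),
    genotypes = geno,
    gen_var = gen_var,
    selection_history = dplyr::bind_rows(history),
    config = config, seed = seed
  ), class = "sim_population")
}

# phenotype criterion for parent selection: one record per candidate, no
# contemporary-group structure (selection acts within a cohort).
sim_selection_phenotype <- function(prev, u, config) {
  u[prev$id] + stats::rnorm(nrow(prev), 0, sqrt(config$sigma2_e))
}

sim_selection_ebv <- function(ped, prev, u, config) {
  vc <- variance_components(config$sigma2_u, config$sigma2_e)
  records <- tibble::tibble(
    id = ped$id,
    y = u[ped$id] + stats::rnorm(nrow(ped), 0, sqrt(config$sigma2_e)))
  K <- nrm(as_pedigree(ped))
  fit <- solve_mme(records, K, vc, pev = FALSE)
  fit$u[prev$id]
}

# extend the TBV vector for newly added individuals (parents already drawn)
sim_extend_tbv <- function(ped_new, u, F, sigma2_u) {
  new_ids <- setdiff(ped_new$id, names(u))
  idx <- match(new_ids, ped_new$id)
  s <- match(ped_new$sire[idx], ped_new$id)
  d <- match(ped_new$dam[idx], ped_new$id)
  ms_var <- sigma2_u * (1 -
    ifelse(is.na(s), 0, 0.25 * (1 + F[pmax(s, 1L)])) -
    ifelse(is.na(d), 0, 0.25 * (1 + F[pmax(d, 1L)])))
  pa <- 0.5 * ifelse(is.na(s), 0, u[ped_new$id[pmax(s, 1L)]]) +
        0.5 * ifelse(is.na(d), 0, u[ped_new$id[pmax(d, 1L)]])
  u_new <- pa + stats::rnorm(length(new_ids), 0, sqrt(pmax(ms_var, 0)))
  c(u, stats::setNames(u_new, new_ids))
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf(
    "simulated population: %d individuals, %d generations, %d phenotyped records%s\n",
    nrow(x$pedigree), max(x$pedigree$generation) + 1, nrow(x$phenotypes),
    if (!is.null(x$genotypes)) sprintf(", %d loci", ncol(x$genotypes)) else ""))
  invisible(x)
}
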