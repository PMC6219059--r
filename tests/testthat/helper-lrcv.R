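# shared fixtures, built in code

vc04 <- variance_components(0.4, 0.6)

# two founders and their offspring
trio_pedigree <- function() {
  as_pedigree(data.frame(id = c("s", "d", "o"),
                         sire = c("0", "0", "s"),
                         dam = c("0", "0", "d")))
}

# two founders, n full sibs
fullsib_pedigree <- function(n_sibs = 2) {
  as_pedigree(data.frame(
    id = c("s", "d", sprintf("o%02d", seq_len(n_sibs))),
    sire = c("0", "0", rep("s", n_sibs)),
    dam = c("0", "0", rep("d", n_sibs))))
}

# chain of t generations of repeated full-sib matings
fullsib_chain_pedigree <- function(t_gen) {
  id <- c("m0", "f0")
  sire <- c("0", "0")
  dam <- c("0", "0")
  for (t in seq_len(t_gen)) {
    id <- c(id, paste0(c("m", "f"), t))
    sire <- c(sire, rep(paste0("m", t - 1), 2))
    dam <- c(dam, rep(paste0("f", t - 1), 2))
  }
  as_pedigree(data.frame(id, sire, dam))
}

# random multi-family pedigree for property tests
random_family_pedigree <- function(n_fam = 10, sibs = 4) {
  sires <- sprintf("FS%02d", seq_len(n_fam))
  dams <- sprintf("FD%02d", seq_len(n_fam))
  off <- sprintf("O%02d_%02d", rep(seq_len(n_fam), each = sibs),
                 rep(seq_len(sibs), n_fam))
  as_pedigree(data.frame(
    id = c(sires, dams, off),
    sire = c(rep("0", 2 * n_fam), rep(sires, each = sibs)),
    dam = c(rep("0", 2 * n_fam), rep(dams, each = sibs))))
}

# small unselected population with phenotypes on the offspring generation
small_population <- function(seed = 1, n_sires = 8, n_dams = 40,
                             n_groups = 4, n_loci = 0, h2 = 0.4) {
  cfg <- sim_config(n_sires = n_sires, n_dams = n_dams, n_groups = n_groups,
                    n_loci = n_loci, sigma2_u = h2, sigma2_e = 1 - h2)
  simulate_population(cfg, seed = seed)
}

expect_within_3se <- function(values, expected, label = NULL) {
  se <- stats::sd(values) / sqrt(length(values))
  expect_lt(abs(mean(values) - expected), 3 * se + 1e-12, label = label)
}
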