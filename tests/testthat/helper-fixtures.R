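# Shared fixtures and independent oracles.

# Quick annotation-table builder with sensible defaults.
make_annotations <- function(n, site_id = "S1", timepoint = "T0",
                             phylum = "Porifera", otu = "sp1",
                             x = seq_len(n), y = seq_len(n),
                             growth = 0, tissue_loss = 0, biofouling = 0,
                             orientation = 0, id_prefix = timepoint) {
  tibble::tibble(
    individual_id = paste0(id_prefix, "-", seq_len(n)),
    site_id = site_id, timepoint = timepoint, phylum = phylum, otu = otu,
    x_m = x, y_m = y, depth_m = 800,
    growth = growth, tissue_loss = tissue_loss, biofouling = biofouling,
    orientation = orientation
  )
}

# Brute-force exact signed-rank p-value: enumerate all 2^n sign assignments
# over the midranks of |d| (zeros must already be dropped).
brute_signed_rank_p <- function(d, alternative) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  eps <- 1e-9
  p_ge <- mean(v_all >= v_obs - eps)
  p_le <- mean(v_all <= v_obs + eps)
  switch(alternative,
    greater = p_ge,
    less = p_le,
    two_sided = min(1, 2 * min(p_ge, p_le))
  )
}

# Brute-force exact rank-sum p-value: enumerate all size-n_a subsets of the
# pooled midranks.
brute_rank_sum_p <- function(a, b, alternative) {
  n_a <- length(a)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n_a)])
  subsets <- utils::combn(length(r), n_a)
  w_all <- apply(subsets, 2, function(idx) sum(r[idx]))
  eps <- 1e-9
  p_ge <- mean(w_all >= w_obs - eps)
  p_le <- mean(w_all <= w_obs + eps)
  switch(alternative,
    greater = p_ge,
    less = p_le,
    two_sided = min(1, 2 * min(p_ge, p_le))
  )
}

# Metric score distributions with all probability mass on zero (no change).
zero_change_distributions <- function() {
  lapply(default_metric_distributions(), function(ph) {
    lapply(ph, function(p) c(1, rep(0, length(p) - 1)))
  })
}

# A tiny two-site simulation bundle used by pipeline tests.
small_bundle <- function(seed = 7,
                         survival_prob = c(Porifera = 0.9, Cnidaria = 0.9),
                         position_jitter_sd = 0.05,
                         metric_distributions = default_metric_distributions()) {
  ab <- tibble::tibble(
    otu = c("spongeA", "spongeB", "coralA"),
    phylum = c("Porifera", "Porifera", "Cnidaria"),
    n_t0 = c(12, 8, 10)
  )
  cfgs <- list(
    site_sim_config("S1", seamount = "M1", o2_mean_t0 = 0.2, o2_mean_t1 = 0.3,
                    otu_abundances = ab, area_m2 = 900, min_spacing = 2,
                    position_jitter_sd = position_jitter_sd,
                    survival_prob = survival_prob,
                    metric_distributions = metric_distributions,
                    recruit_rate = c(spongeA = 1)),
    site_sim_config("S2", seamount = "M2", o2_mean_t0 = 1.2, o2_mean_t1 = 1.1,
                    otu_abundances = ab, area_m2 = 900, min_spacing = 2,
                    position_jitter_sd = position_jitter_sd,
                    survival_prob = survival_prob,
                    metric_distributions = metric_distributions)
  )
  generate_study(cfgs, seed = seed)
}
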