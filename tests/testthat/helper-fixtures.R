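# shared fixtures, all generated in code

# compact generator config: 31 IDPs total (12 sMRI, 9 dMRI, 10 rsfMRI edges)
small_config <- function(n = 300, seed = 1, ...) {
  generator_config(n_subjects = n,
                   block_sizes = c(sMRI = 12L, dMRI = 9L),
                   n_networks = 5L, seed = seed, ...)
}

# hand-written 2-IDP schema for toy IO tests
toy_schema <- function() {
  cohort_schema(modality_blocks = list(sMRI = c("gmv_001"), dMRI = c("fa_01"),
                                       rsfMRI = c("fc_01_02")))
}

toy_cohort_df <- function(n = 3) {
  set.seed(42)
  data.frame(subject_id = sprintf("T%02d", seq_len(n)),
             age = seq(50, 70, length.out = n),
             sex = rep_len(c(0L, 1L), n),
             education_years = rep_len(c(12L, 16L, 20L), n),
             gmv_001 = rnorm(n), fa_01 = rnorm(n), fc_01_02 = rnorm(n),
             pairs_matching = rnorm(n, 3.6), numeric_memory = rnorm(n, 6.8),
             fluid_intelligence = rnorm(n, 6.8),
             paired_associate_learning = rnorm(n, 7.2),
             matrix_completion = rnorm(n, 8.2),
             reaction_time = exp(rnorm(n, 6.3, 0.1)),
             symbol_digit = rnorm(n, 19.6), tower_rearranging = rnorm(n, 10),
             trail_making = exp(rnorm(n, 6.2, 0.1)),
             systolic_bp = rnorm(n, 135, 10), driving_time = runif(n, 0.5, 2),
             grip_strength = rnorm(n, 35, 5),
             physical_activity = runif(n, 10, 40),
             walking_pace = rep_len(1:3, n), diabetes = rep_len(c(0L, 1L), n),
             stringsAsFactors = FALSE)
}

# cohort whose age is an exact linear function of three IDPs:
# smri_001..smri_003 carry the signal, the rest are pure noise
exact_linear_cohort <- function(n = 200, seed = 1) {
  sim <- generate_cohort(small_config(n = n, seed = seed))
  co <- sim$cohort
  age <- co$data$age
  co$data$smri_001 <- 0.5 * age
  co$data$smri_002 <- -0.2 * age + 3
  co$data$smri_003 <- 0.1 * age - 1
  co
}

# compact end-to-end pipeline configuration reused by the determinism checks
pipeline_test_config <- function(dir, seed = 5) {
  run_config(generator = small_config(n = 420, seed = 99,
                                      subtype_effect_size = 2.5,
                                      n_subtypes = 2L),
             output_dir = dir, k_range = 2:3, n_folds = 3L, n_init = 2L,
             cluster_targets = "truth", seed = seed)
}

# separable two-cluster toy in the plane: targets in two antipodal clouds on
# either side of a control cloud at the origin
separable_toy <- function(n_per = 6, n_controls = 20, sep = 6, sd = 0.3,
                          seed = 1) {
  set.seed(seed)
  xc <- matrix(rnorm(n_controls * 2, 0, sd), n_controls, 2)
  xt <- rbind(cbind(rnorm(n_per, sep, sd), rnorm(n_per, 0, sd)),
              cbind(rnorm(n_per, -sep, sd), rnorm(n_per, 0, sd)))
  list(x = rbind(xc, xt),
       is_target = c(rep(FALSE, n_controls), rep(TRUE, 2 * n_per)),
       truth = rep(1:2, each = n_per))
}

# total polytope objective for a fixed assignment of targets to K faces,
# scoring each face with an independently (cold-started) fitted classifier;
# used by the exhaustive-enumeration oracle
score_assignment <- function(xc, xt, assign, K, C = 1) {
  total <- 0
  for (j in seq_len(K)) {
    rows <- which(assign == j)
    xf <- rbind(xc, xt[rows, , drop = FALSE])
    yf <- c(rep(-1, nrow(xc)), rep(1, length(rows)))
    sf <- c(rep(1 / K, nrow(xc)), rep(1, length(rows)))
    total <- total + svm_squared_hinge(xf, yf, sf, C = C, gtol = 1e-8)$objective
  }
  total
}

# brute-force optimum over all assignments of nt targets to K=2 faces with
# both faces nonempty; face-swap symmetry halves the enumeration
exhaustive_polytope_objective <- function(xc, xt, C = 1) {
  nt <- nrow(xt)
  best <- Inf
  for (code in 0:(2^(nt - 1) - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(nt)]
    assign <- bits + 1L
    if (all(assign == 1L)) next
    best <- min(best, score_assignment(xc, xt, assign, 2L, C = C))
  }
  best
}

# independent pair-counting ARI oracle: loops over all pairs of elements
ari_pair_counting <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  total <- choose(n, 2)
  exp_index <- (n11 + n10) * (n11 + n01) / total
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  (n11 - exp_index) / (max_index - exp_index)
}
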