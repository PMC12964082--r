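fixture_path <- function(name) {
  system.file("extdata", name, package = "handtrans", mustWork = TRUE)
}

load_familial_fixture <- function(mode = "reported") {
  read_familial_table(fixture_path("synthetic_familial_17studies.csv"),
                      incidence_mode = mode)
}

load_twin_fixture <- function() {
  read_twin_table(fixture_path("twin_pairs_reconstructed.csv"))
}

load_sex_fixture <- function() {
  read_sex_table(fixture_path("synthetic_sex_stratified.csv"))
}

# build a familial_data frame in code
make_familial <- function(counts, pairs = NULL, m_p = NA_real_,
                          ids = NULL, mode = "reported") {
  counts <- rbind(counts)
  df <- data.frame(
    study_id = if (is.null(ids)) sprintf("s%02d", seq_len(nrow(counts)))
               else ids,
    rxr_r = counts[, 1], rxr_l = counts[, 2],
    mix_r = counts[, 3], mix_l = counts[, 4],
    lxl_r = counts[, 5], lxl_l = counts[, 6])
  if (is.null(pairs)) {
    df$pairs_rxr <- round((df$rxr_r + df$rxr_l) / 3)
    df$pairs_mix <- round((df$mix_r + df$mix_l) / 3)
    df$pairs_lxl <- round((df$lxl_r + df$lxl_l) / 3)
  } else {
    pairs <- rbind(pairs)
    df$pairs_rxr <- pairs[, 1]; df$pairs_mix <- pairs[, 2]
    df$pairs_lxl <- pairs[, 3]
  }
  df$m_p <- m_p
  structure(df, class = c("familial_data", "data.frame"),
            incidence_mode = mode)
}

# random feasible base parameters
random_base_params <- function(beta_free = FALSE) {
  rho <- runif(1, 0, 0.5)
  alpha <- runif(1, 0, 0.5 - rho)
  beta <- if (beta_free) runif(1, -0.2, min(0.2, 0.5 - rho)) else 0
  base_params(rho, alpha, beta)
}
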