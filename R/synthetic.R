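#' Parameters of a synthetic double-mutant fitness screen
#'
#' Collects the generative settings of [simulate_screen()]. The defaults
#' describe a mid-sized screen whose non-interacting pairs follow the
#' multiplicative model exactly before noise: single-mutant fitness is drawn
#' from a normal distribution centred at 1 (truncated to `[0.05, 1.5]`, so
#' the generated fitness values have median close to unity as in
#' median-normalized screens), about 3% of pairs carry a planted interaction
#' (half alleviating, half aggravating, matching the empirical interaction
#' rate of unbiased screens), measurement noise is multiplicative
#' log-normal, and a small share of cells is missing completely at random.
#' A fraction of strains can be duplicated (with independent noise) to
#' exercise duplicate merging.
#'
#' @param m,n Numbers of query and array strains.
#' @param fitness_mean,fitness_sd Location and spread of the single-mutant
#'   fitness distribution before truncation.
#' @param fitness_bounds Truncation bounds of single-mutant fitness.
#' @param rho_pos,rho_neg Fractions of pairs carrying planted positive /
#'   negative interactions (`rho_pos + rho_neg < 0.5`).
#' @param gamma_pos_range Range of multiplicative alleviation factors
#'   (`> 1`): a planted positive pair has fitness `gamma * x[a] * y[b]`.
#' @param gamma_neg_range Range of aggravation factors in `[0, 1)`.
#' @param lethal_fraction Share of planted negatives set fully lethal
#'   (`w = 0`), the extreme aggravating case.
#' @param noise_sd Standard deviation of the log-scale multiplicative noise.
#' @param missing_fraction Probability that a cell is missing (MCAR).
#' @param duplicate_fraction Share of query and of array strains measured
#'   twice (independent noise, same identifier).
#' @param seed Integer seed; the whole screen is reproducible from it.
#' @return A list of class `screen_params`.
#' @export
screen_params <- function(m = 200, n = 100,
                          fitness_mean = 1.0, fitness_sd = 0.15,
                          fitness_bounds = c(0.05, 1.5),
                          rho_pos = 0.015, rho_neg = 0.015,
                          gamma_pos_range = c(1.3, 2.0),
                          gamma_neg_range = c(0, 0.6),
                          lethal_fraction = 0.3,
                          noise_sd = 0.1,
                          missing_fraction = 0.05,
                          duplicate_fraction = 0.02,
                          seed = 1L) {
  p <- list(
    m = as.integer(m), n = as.integer(n),
    fitness_mean = fitness_mean, fitness_sd = fitness_sd,
    fitness_bounds = fitness_bounds,
    rho_pos = rho_pos, rho_neg = rho_neg,
    gamma_pos_range = gamma_pos_range, gamma_neg_range = gamma_neg_range,
    lethal_fraction = lethal_fraction, noise_sd = noise_sd,
    missing_fraction = missing_fraction,
    duplicate_fraction = duplicate_fraction, seed = as.integer(seed)
  )
  validate_screen_params(p)
  structure(p, class = "screen_params")
}

validate_screen_params <- function(p) {
  if (p$m < 1 || p$n < 1) stop("m and n must be positive", call. = FALSE)
  if (p$rho_pos < 0 || p$rho_neg < 0 || p$rho_pos + p$rho_neg >= 0.5) {
    stop("planted fractions must be non-negative with rho_pos + rho_neg < 0.5",
      call. = FALSE
    )
  }
  for (fr in c(p$lethal_fraction, p$missing_fraction, p$duplicate_fraction)) {
    if (fr < 0 || fr > 1) stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (diff(p$fitness_bounds) <= 0 || p$fitness_bounds[1] < 0) {
    stop("fitness_bounds must be ordered and non-negative", call. = FALSE)
  }
  if (diff(p$gamma_pos_range) < 0 || p$gamma_pos_range[1] <= 1) {
    stop("gamma_pos_range must be ordered with lower bound > 1", call. = FALSE)
  }
  if (diff(p$gamma_neg_range) < 0 || p$gamma_neg_range[1] < 0 ||
    p$gamma_neg_range[2] >= 1) {
    stop("gamma_neg_range must be ordered within [0, 1)", call. = FALSE)
  }
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  invisible(p)
}

# truncated normal via inverse-CDF so draw count is deterministic
rtrunc_norm <- function(k, mean, sd, bounds) {
  lo <- stats::pnorm(bounds[1], mean, sd)
  hi <- stats::pnorm(bounds[2], mean, sd)
  stats::qnorm(stats::runif(k, lo, hi), mean, sd)
}

# ground truth shared by replicate screens: single-mutant fitness vectors,
# planted masks and per-pair interaction factors
make_truth <- function(params, seed) {
  set.seed(seed)
  m <- params$m
  n <- params$n
  x <- rtrunc_norm(m, params$fitness_mean, params$fitness_sd, params$fitness_bounds)
  y <- rtrunc_norm(n, params$fitness_mean, params$fitness_sd, params$fitness_bounds)
  names(x) <- sprintf("q%04d", seq_len(m))
  names(y) <- sprintf("a%04d", seq_len(n))
  n_pos <- round(params$rho_pos * m * n)
  n_neg <- round(params$rho_neg * m * n)
  planted <- sample.int(m * n, n_pos + n_neg)
  pos_idx <- planted[seq_len(n_pos)]
  neg_idx <- planted[n_pos + seq_len(n_neg)]
  gamma <- matrix(1, m, n, dimnames = list(names(x), names(y)))
  gamma[pos_idx] <- stats::runif(n_pos, params$gamma_pos_range[1], params$gamma_pos_range[2])
  gamma[neg_idx] <- stats::runif(n_neg, params$gamma_neg_range[1], params$gamma_neg_range[2])
  n_lethal <- round(params$lethal_fraction * n_neg)
  if (n_lethal > 0) gamma[sample(neg_idx, n_lethal)] <- 0
  pos_mask <- neg_mask <- matrix(FALSE, m, n, dimnames = dimnames(gamma))
  pos_mask[pos_idx] <- TRUE
  neg_mask[neg_idx] <- TRUE
  list(x = x, y = y, gamma = gamma, pos_mask = pos_mask, neg_mask = neg_mask)
}

# one noisy realization of the clean matrix: log-normal noise, clipping,
# MCAR missingness
realize_cells <- function(clean, params) {
  w <- clean * exp(stats::rnorm(length(clean), 0, params$noise_sd))
  w <- pmax(w, 0)
  w[stats::runif(length(clean)) < params$missing_fraction] <- NA_real_
  matrix(w, nrow(clean), ncol(clean), dimnames = dimnames(clean))
}

realize_screen <- function(truth, params, seed, name) {
  set.seed(seed)
  clean <- outer(truth$x, truth$y) * truth$gamma
  W <- realize_cells(clean, params)
  k_r <- round(params$duplicate_fraction * params$m)
  k_c <- round(params$duplicate_fraction * params$n)
  if (k_r > 0 || k_c > 0) {
    W2 <- realize_cells(clean, params) # independent re-measurement
    dup_r <- if (k_r > 0) sort(sample.int(params$m, k_r)) else integer(0)
    dup_c <- if (k_c > 0) sort(sample.int(params$n, k_c)) else integer(0)
    if (k_r > 0) W <- rbind(W, W2[dup_r, , drop = FALSE])
    if (k_c > 0) W <- cbind(W, W2[c(seq_len(params$m), dup_r), dup_c, drop = FALSE])
  }
  fm <- fitness_matrix(W, name = name)
  structure(
    list(
      fm = fm, true_x = truth$x, true_y = truth$y,
      pos_mask = truth$pos_mask, neg_mask = truth$neg_mask, params = params
    ),
    class = "synthetic_screen"
  )
}

#' Simulate a double-mutant fitness screen with planted interactions
#'
#' Generates a fitness matrix whose non-interacting cells follow the
#' multiplicative model `w[a, b] = x[a] * y[b]` exactly before noise, with
#' planted positive and negative interactions applied as multiplicative
#' factors, log-normal measurement noise, missing cells, and optional
#' duplicated strains. The ground truth (single-mutant vectors, planted
#' masks) is returned alongside the matrix so recovery and detection can be
#' evaluated.
#'
#' @param params A `screen_params` object.
#' @param name Dataset label for the generated matrix.
#' @return A `synthetic_screen`: list with `fm` (a `fitness_matrix`,
#'   possibly containing duplicated strain identifiers), `true_x`, `true_y`,
#'   `pos_mask`, `neg_mask` (logical `m x n` matrices over the unique
#'   identifiers), and `params`.
#' @examples
#' scr <- simulate_screen(screen_params(m = 40, n = 30, seed = 7))
#' scr$fm
#' @export
simulate_screen <- function(params = screen_params(), name = "synthetic") {
  validate_screen_params(params)
  set.seed(params$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2)
  truth <- make_truth(params, seeds[1])
  realize_screen(truth, params, seeds[2], name)
}

#' Simulate two replicate screens sharing the same ground truth
#'
#' Both screens share the single-mutant fitness vectors, the planted
#' interaction masks and the per-pair interaction strengths; measurement
#' noise, missingness and strain duplication are drawn independently. This
#' emulates two screening platforms assaying the same underlying genetic
#' network, the setting in which rank aggregation across screens is
#' expected to help.
#'
#' @param params A `screen_params` object.
#' @param shared_truth_seed Seed for the shared ground truth.
#' @param noise_seeds Integer vector of length 2, one noise seed per screen;
#'   by default derived from `shared_truth_seed`.
#' @return A list of two `synthetic_screen` objects with identical `true_x`,
#'   `true_y` and masks.
#' @export
simulate_replicate_pair <- function(params = screen_params(),
                                    shared_truth_seed = params$seed,
                                    noise_seeds = NULL) {
  validate_screen_params(params)
  if (is.null(noise_seeds)) {
    # offsets wrapped into the valid integer seed range
    noise_seeds <- as.integer(
      (as.numeric(shared_truth_seed) + c(1, 2)) %% (.Machine$integer.max - 1)
    )
  }
  truth <- make_truth(params, shared_truth_seed)
  list(
    realize_screen(truth, params, noise_seeds[1], "replicate_1"),
    realize_screen(truth, params, noise_seeds[2], "replicate_2")
  )
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat(sprintf(
    "<synthetic_screen> %d x %d measured (%d x %d unique); %d positive, %d negative planted pairs\n",
    nrow(x$fm), ncol(x$fm), x$params$m, x$params$n,
    sum(x$pos_mask), sum(x$neg_mask)
  ))
  invisible(x)
}
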