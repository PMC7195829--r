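# Shared fixtures and independent oracles used across test files.

RES20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal property table: one property with value(A)=1, value(C)=3, rest 0;
# one constant property with value 2.5 everywhere.
tiny_aaindex <- function() {
  m <- matrix(0, nrow = 2, ncol = 20, dimnames = list(c("p_ac", "p_const"), RES20))
  m["p_ac", "A"] <- 1
  m["p_ac", "C"] <- 3
  m["p_const", ] <- 2.5
  m
}

tiny_catalog <- function(n = 6) sprintf("DOMX%03d", seq_len(n))

# Independent GM(2,1) oracle: builds the same design by hand and solves the
# least-squares problem through an explicit SVD pseudo-inverse (no MASS).
oracle_gm21 <- function(x0) {
  L <- length(x0)
  x1 <- cumsum(x0)
  Y <- x0[-1] - x0[-L]
  z <- (x1[-1] + x1[-L]) / 2
  B <- cbind(-x0[-1], -z, 1)
  s <- svd(B)
  pos <- s$d > max(dim(B)) * max(s$d) * .Machine$double.eps
  dinv <- ifelse(pos, 1 / s$d, 0)
  as.numeric(s$v %*% (dinv * (t(s$u) %*% Y)))
}

# Brute-force plug-in mutual information over the joint histogram (bits).
oracle_mi <- function(x, y) {
  n <- length(x)
  ux <- unique(x)
  uy <- unique(y)
  total <- 0
  for (a in ux) {
    for (b in uy) {
      pab <- sum(x == a & y == b) / n
      if (pab > 0) {
        total <- total + pab * log2(pab / ((sum(x == a) / n) * (sum(y == b) / n)))
      }
    }
  }
  total
}

# Small directly-constructed feature matrix: two informative columns
# (noisy copies of the label) plus pure-noise columns.
toy_informative_data <- function(n_per_class = 60, p_noise = 3, seed = 42) {
  withr::with_seed(seed, {
    y <- factor(rep(c("nonECM", "ECM"), each = n_per_class),
                levels = c("nonECM", "ECM"))
    signal <- as.numeric(y == "ECM")
    x <- cbind(f1 = signal + rnorm(2 * n_per_class, sd = 0.3),
               f2 = signal + rnorm(2 * n_per_class, sd = 0.5),
               matrix(rnorm(2 * n_per_class * p_noise),
                      ncol = p_noise,
                      dimnames = list(NULL, sprintf("noise%d", seq_len(p_noise)))))
    list(x = x, y = y)
  })
}

# Attenuated-signal generator condition used for the imbalance experiments:
# classes overlap enough that a learner is imperfect, so the damage done by
# class imbalance (and the repair by the under-sampling ensemble) is visible.
moderate_sim_config <- function(seed, n_pos = 40, n_neg = 840) {
  sim_config(n_pos = n_pos, n_neg = n_neg, seq_len_range = c(40L, 120L),
             p_domain_pos = 0.03, p_domain_neg = 0.015,
             composition_shift = 0.04, pssm_signal = 0.5, seed = seed)
}

# Null condition: no class-dependent signal anywhere.
null_sim_config <- function(seed, n_pos = 60, n_neg = 120) {
  sim_config(n_pos = n_pos, n_neg = n_neg, seq_len_range = c(40L, 120L),
             p_domain_pos = 0.02, p_domain_neg = 0.02,
             composition_shift = 0, pssm_signal = 0, seed = seed)
}

fast_config <- function(seed = 1, ...) {
  ensemble_config(n_trees = 100L, seed = seed, ...)
}
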