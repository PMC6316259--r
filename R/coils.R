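# Heptad-position propensity table for the sliding-window coiled-coil
# scorer. Rows are amino acids, columns the heptad registers a-g. Values are
# relative preferences: hydrophobic residues (L, I, M, V) favor the core
# positions a/d, charged/polar residues (E, Q, K, R) the solvent-exposed
# b/c/e/f/g positions, and proline is strongly disfavored everywhere.
# The scorer is a simplified Lupas-style detector used as a boolean CC
# caller at a probability threshold; it is not bit-compatible with COILS,
# and precomputed COILS calls can be supplied through the domain table
# instead.
coil_propensities <- function() {
  tab <- matrix(c(
    # a     b     c     d     e     f     g
    3.17, 0.51, 0.52, 3.90, 0.54, 0.55, 0.57, # L
    2.60, 0.45, 0.47, 0.89, 0.40, 0.48, 0.43, # I
    2.25, 0.60, 0.64, 1.89, 0.66, 0.63, 0.61, # M
    1.82, 0.56, 0.58, 0.94, 0.51, 0.57, 0.54, # V
    1.30, 1.07, 1.12, 1.23, 1.10, 1.09, 1.07, # A
    0.86, 0.51, 0.55, 1.22, 0.54, 0.57, 0.55, # F
    0.76, 0.71, 0.74, 0.89, 0.72, 0.73, 0.71, # Y
    0.61, 0.52, 0.54, 0.77, 0.55, 0.57, 0.53, # W
    0.60, 1.55, 1.48, 0.65, 1.73, 1.42, 1.50, # E
    0.83, 1.32, 1.28, 0.77, 1.35, 1.25, 1.45, # Q
    0.65, 1.25, 1.22, 0.61, 1.31, 1.28, 1.57, # K
    0.68, 1.18, 1.20, 0.66, 1.25, 1.22, 1.38, # R
    0.78, 1.02, 1.04, 0.69, 1.01, 1.03, 1.00, # N
    0.52, 1.10, 1.08, 0.48, 1.07, 1.12, 1.02, # D
    0.75, 0.96, 0.98, 0.70, 0.94, 0.97, 0.95, # S
    0.78, 0.91, 0.92, 0.74, 0.89, 0.92, 0.90, # T
    0.66, 0.96, 0.95, 0.63, 0.94, 0.97, 0.95, # H
    0.72, 0.55, 0.57, 0.86, 0.54, 0.56, 0.55, # C
    0.42, 0.56, 0.57, 0.39, 0.55, 0.58, 0.56, # G
    0.02, 0.09, 0.10, 0.02, 0.09, 0.10, 0.09  # P
  ), ncol = 7, byrow = TRUE)
  rownames(tab) <- c("L", "I", "M", "V", "A", "F", "Y", "W", "E", "Q",
                     "K", "R", "N", "D", "S", "T", "H", "C", "G", "P")
  colnames(tab) <- letters[1:7]
  tab
}

# Per-window-length parameters of the two-Gaussian (coiled-coil vs globular)
# score model. Globular means/SDs were fitted once on window-score maxima of
# random sequences at typical globular amino-acid composition; coiled-coil
# means/SDs on idealized heptad repeats with exposed-position variability.
# The weight reflects the rarity of coiled-coil windows among all windows.
coil_score_params <- list(
  `14` = list(m_cc = 1.60, sd_cc = 0.14, m_g = 0.90, sd_g = 0.14, w = 20),
  `21` = list(m_cc = 1.60, sd_cc = 0.12, m_g = 0.86, sd_g = 0.12, w = 25),
  `28` = list(m_cc = 1.60, sd_cc = 0.10, m_g = 0.84, sd_g = 0.10, w = 30)
)

#' Score coiled-coil propensity along a protein
#'
#' Lupas-style sliding-window scorer: each window of length `window` is
#' scored as the geometric mean of per-position heptad propensities from the
#' bundled table, maximized over the seven possible register phases; the
#' window score is mapped to a [0,1] probability through a two-Gaussian
#' (coiled-coil vs globular) likelihood ratio with bundled means and SDs.
#' Each residue receives the maximum probability over all windows covering
#' it, and a CC call is any maximal run of residues at or above `threshold`.
#'
#' @param protein Amino-acid string, length at least `window`.
#' @param window Window length: 14, 21 or 28 residues (default 21).
#' @param threshold Probability above which residues are called coiled-coil
#'   (default 0.9, the conventional cutoff).
#' @return A `coiled_coil_profile`: list with `per_residue_score` (numeric,
#'   one value per residue, in [0,1]), `window`, `threshold`, and `calls`, a
#'   data.frame of maximal runs (`start`, `end`, 1-based amino-acid
#'   coordinates) with score >= threshold.
#' @export
coiled_coil_score <- function(protein, window = 21, threshold = 0.9) {
  if (!window %in% c(14, 21, 28)) stop("window must be 14, 21 or 28",
                                       call. = FALSE)
  aa <- strsplit(toupper(protein), "")[[1]]
  n <- length(aa)
  if (n < window) stop("protein shorter than window", call. = FALSE)
  tab <- coil_propensities()
  unknown <- !(aa %in% rownames(tab))
  if (any(unknown)) {
    message(sum(unknown), " non-standard residue(s) scored with neutral propensity 1.0")
  }
  # log-propensity matrix: 7 phases x n residues
  logp <- matrix(0, nrow = 7, ncol = n)
  idx <- match(aa, rownames(tab))
  for (ph in 0:6) {
    reg <- ((seq_len(n) - 1 + ph) %% 7) + 1
    v <- tab[cbind(idx, reg)]
    v[is.na(v)] <- 1.0
    logp[ph + 1, ] <- log(v)
  }
  nw <- n - window + 1
  # cumulative sums per phase for O(1) window sums
  win_best <- numeric(nw)
  cs <- cbind(0, t(apply(logp, 1, cumsum)))
  for (i in seq_len(nw)) {
    sums <- cs[, i + window] - cs[, i]
    win_best[i] <- max(sums) / window
  }
  win_score <- exp(win_best)
  par <- coil_score_params[[as.character(window)]]
  num <- dnorm(win_score, par$m_cc, par$sd_cc)
  den <- num + par$w * dnorm(win_score, par$m_g, par$sd_g)
  win_prob <- ifelse(den == 0, as.numeric(win_score > par$m_g), num / den)
  per_res <- numeric(n)
  for (i in seq_len(nw)) {
    rng <- i:(i + window - 1)
    per_res[rng] <- pmax(per_res[rng], win_prob[i])
  }
  above <- per_res >= threshold
  calls <- if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    data.frame(start = starts[r$values], end = ends[r$values])
  } else {
    data.frame(start = integer(0), end = integer(0))
  }
  structure(list(per_residue_score = per_res, window = window,
                 threshold = threshold, calls = calls),
            class = "coiled_coil_profile")
}
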