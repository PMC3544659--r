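# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: explicit per-pixel loops and direct formulas.

hdab <- ihcscore::stain_matrix("hdab")

# forward-render an RGB image from concentration matrices with explicit
# scalar arithmetic (no package internals)
render_oracle <- function(cd, ch, M = hdab, bg = c(255, 255, 255)) {
  H <- nrow(cd); W <- ncol(cd)
  rgb <- array(0L, c(H, W, 3))
  for (chan in 1:3) {
    od <- M[chan, 1] * ch + M[chan, 2] * cd
    rgb[, , chan] <- pmin(pmax(floor(bg[chan] * 10^(-od) + 0.5), 0), 255)
  }
  rgb
}

# per-pixel zone classification loop
zone_oracle <- function(dab, zones = c(60, 120, 170, 230)) {
  n <- c(n3 = 0L, n2 = 0L, n1 = 0L, n0 = 0L, n_excluded = 0L)
  for (v in as.integer(dab)) {
    if (v <= zones[1]) n["n3"] <- n["n3"] + 1L
    else if (v <= zones[2]) n["n2"] <- n["n2"] + 1L
    else if (v <= zones[3]) n["n1"] <- n["n1"] + 1L
    else if (v <= zones[4]) n["n0"] <- n["n0"] + 1L
    else n["n_excluded"] <- n["n_excluded"] + 1L
  }
  n
}

# Cohen's kappa straight from the 4x4 cross-table definition
kappa_oracle <- function(manual, auto) {
  lv <- c("0", "1+", "2+", "3+")
  tab <- table(factor(manual, lv), factor(auto, lv))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

# Pearson chi-square statistic straight from sum((O-E)^2/E)
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# uniform histogram image builder
uniform_dab <- function(value, n = 100L) matrix(as.integer(value), 10L, n / 10L)

# histogram object straight from four zone counts (for rule-level tests)
hist_from_counts <- function(n3, n2, n1, n0, n_excluded = 0L) {
  dab <- matrix(c(rep(40L, n3), rep(90L, n2), rep(150L, n1),
                  rep(200L, n0), rep(240L, n_excluded)), nrow = 1L)
  ihcscore::zone_histogram(dab)
}
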