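# shared fixtures built in code

# default frequency axis for Pake-pattern tests: 0.05 kHz bins covering
# the feet of couplings up to 25 kHz after Lee-Goldburg scaling
pake_grid <- function(bin = 0.05, span = 30) seq(-span, span, by = bin)

# log-spaced relaxation delays
log_delays <- function(n = 12, lo = 0.01, hi = 5) exp(seq(log(lo), log(hi), length.out = n))

# a minimal MAGRES file with given diagonal shielding tensors
write_magres_fixture <- function(path, labels, diags) {
  lines <- c("#$magres-abinitio-v1.0", "[magres]")
  for (i in seq_along(labels)) {
    d <- diags[[i]]
    lines <- c(lines, sprintf("ms %s %d  %g 0 0  0 %g 0  0 0 %g",
                              labels[i], i, d[1], d[2], d[3]))
  }
  writeLines(c(lines, "[/magres]"), path)
  path
}

# brute-force periodic minimum distance over all images in -n..n
brute_min_image <- function(cell, fa, fb, n = 2) {
  M <- cell_matrix(cell)
  best <- Inf
  for (i in -n:n) for (j in -n:n) for (k in -n:n) {
    d <- (fb + c(i, j, k) - fa) %*% t(M)
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}
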