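# Independent brute-force oracles. These deliberately share no code with the
# package implementation: boundary extraction and distances are computed by
# explicit loops over pixel pairs, and parameter counts by closed-form
# layer-by-layer enumeration.

# Boundary pixels of a 2-d mask under 4-connectivity (out-of-grid = outside).
brute_surface2d <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pts <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!m[i, j]) next
    nb_out <- (i == 1 || !m[i - 1, j]) || (i == nr || !m[i + 1, j]) ||
      (j == 1 || !m[i, j - 1]) || (j == nc || !m[i, j + 1])
    if (nb_out) pts <- rbind(pts, c(i, j))
  }
  pts
}

# All-pairs surface distances between two 2-d masks with (y, x) spacing.
brute_distances <- function(A, B, spacing = c(1, 1)) {
  sa <- brute_surface2d(A)
  sb <- brute_surface2d(B)
  dmin_ab <- apply(sa, 1, function(p)
    min(sqrt(((p[1] - sb[, 1]) * spacing[1])^2 + ((p[2] - sb[, 2]) * spacing[2])^2)))
  dmin_ba <- apply(sb, 1, function(p)
    min(sqrt(((p[1] - sa[, 1]) * spacing[1])^2 + ((p[2] - sa[, 2]) * spacing[2])^2)))
  list(hd_ab = max(dmin_ab), hd_ba = max(dmin_ba),
       hd_sym = max(max(dmin_ab), max(dmin_ba)),
       msd = (sum(dmin_ab) + sum(dmin_ba)) / (length(dmin_ab) + length(dmin_ba)))
}

# Closed-form parameter count for the architectures, enumerated layer by
# layer (conv = k^2 * cin * cout + cout).
oracle_conv <- function(k, cin, cout) k * k * cin * cout + cout

oracle_count <- function(spec) {
  w <- spec$stage_widths
  L <- length(w)
  k <- spec$kernel
  g <- spec$growth
  stage <- function(cin, lev) {
    if (spec$dense_blocks == 0) {
      oracle_conv(k, cin, w[lev]) + oracle_conv(k, w[lev], w[lev])
    } else {
      tot <- 0; c0 <- cin
      for (blk in seq_len(spec$dense_blocks)) {
        cc <- c0
        for (l in seq_len(spec$convs_per_block)) {
          tot <- tot + oracle_conv(k, cc, g[lev])
          cc <- cc + g[lev]
        }
        tot <- tot + oracle_conv(1, cc, w[lev])
        c0 <- w[lev]
      }
      tot
    }
  }
  tot <- 0; cin <- 1
  for (lev in seq_len(L)) { tot <- tot + stage(cin, lev); cin <- w[lev] }
  for (lev in (L - 1):1) {
    tot <- tot + oracle_conv(3, w[lev + 1], w[lev])       # 3x3 stride-2 upconv
    tot <- tot + stage(2 * w[lev], lev)
  }
  tot + oracle_conv(1, w[1], spec$n_classes)
}
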