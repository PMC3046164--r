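# Independent oracles used across the test files.

# Closed-form area of the union of two radius-r disks at centre distance d:
# 2*pi*r^2 minus the lens-shaped intersection.
two_disk_union_closed_form <- function(r, d) {
  if (d >= 2 * r) return(2 * pi * r^2)
  lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  2 * pi * r^2 - lens
}

# Brute-force within-subjects two-way ANOVA, written as explicit elementwise
# loops over a complete subjects x A x B array of cell means.  Deliberately
# naive: every marginal mean is recomputed by direct summation.
rm_anova_bruteforce <- function(y) {
  # y: 3-d array [subject, A, B]
  S <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  gm <- sum(y) / (S * a * b)
  m_s <- apply(y, 1, sum) / (a * b)
  m_a <- apply(y, 2, sum) / (S * b)
  m_b <- apply(y, 3, sum) / (S * a)
  m_ab <- apply(y, c(2, 3), sum) / S
  m_as <- apply(y, c(1, 2), sum) / b
  m_bs <- apply(y, c(1, 3), sum) / a
  SS_A <- SS_B <- SS_AB <- SS_AS <- SS_BS <- SS_res <- 0
  for (s in 1:S) for (i in 1:a) for (j in 1:b) {
    SS_A  <- SS_A  + (m_a[i] - gm)^2
    SS_B  <- SS_B  + (m_b[j] - gm)^2
    SS_AB <- SS_AB + (m_ab[i, j] - m_a[i] - m_b[j] + gm)^2
    SS_AS <- SS_AS + (m_as[s, i] - m_a[i] - m_s[s] + gm)^2
    SS_BS <- SS_BS + (m_bs[s, j] - m_b[j] - m_s[s] + gm)^2
    SS_res <- SS_res +
      (y[s, i, j] - m_ab[i, j] - m_as[s, i] - m_bs[s, j] +
         m_a[i] + m_b[j] + m_s[s] - gm)^2
  }
  F_A <- (SS_A / (a - 1)) / (SS_AS / ((a - 1) * (S - 1)))
  F_B <- (SS_B / (b - 1)) / (SS_BS / ((b - 1) * (S - 1)))
  F_AB <- (SS_AB / ((a - 1) * (b - 1))) /
    (SS_res / ((a - 1) * (b - 1) * (S - 1)))
  list(SS_A = SS_A, SS_B = SS_B, SS_AB = SS_AB,
       SS_AS = SS_AS, SS_BS = SS_BS, SS_res = SS_res,
       F_A = F_A, F_B = F_B, F_AB = F_AB)
}

# Build an estimate table straight from a [subject, condition, numerosity]
# array of (possibly replicated) values.
table_from_array <- function(y, conditions = c("first_order", "second_order"),
                             numerosities = NULL) {
  S <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  if (is.null(numerosities)) numerosities <- seq_len(b) + 9L
  out <- expand.grid(subject = 1:S, condition = conditions[1:a],
                     numerosity = numerosities, stringsAsFactors = FALSE)
  out$estimate <- mapply(function(s, cidx, j) y[s, cidx, j],
                         out$subject, match(out$condition, conditions),
                         match(out$numerosity, numerosities))
  out$bar_height <- 2.6
  out$trial <- 1L
  class(out) <- c("estimate_table", "data.frame")
  out
}

# Independent distance-based dilation of a black-texel mask: a texel belongs
# to the dilated set iff its Euclidean distance to some mask texel is at most
# r_tex.  O(mask size x frame size); use with small layouts only.
dilate_by_distance <- function(mask, r_tex) {
  idx <- which(mask, arr.ind = TRUE)
  ny <- nrow(mask); nx <- ncol(mask)
  out <- matrix(FALSE, ny, nx)
  gy <- rep(seq_len(ny), times = nx)
  gx <- rep(seq_len(nx), each = ny)
  covered <- rep(FALSE, ny * nx)
  for (k in seq_len(nrow(idx))) {
    covered <- covered |
      ((gy - idx[k, 1])^2 + (gx - idx[k, 2])^2 <= r_tex^2)
  }
  matrix(covered, ny, nx)
}
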