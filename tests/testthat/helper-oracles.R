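# Independent brute-force oracles, kept deliberately separate from the
# package's code paths: integer-coded base pairing (A=1, C=2, G=3, U=4;
# Watson-Crick iff codes sum to 5, G:U wobble iff codes sum to 7) instead
# of the package's character lookup tables.

.code <- c(A = 1L, C = 2L, G = 3L, U = 4L)

rna_codes <- function(seq) unname(.code[strsplit(seq, "", fixed = TRUE)[[1]]])

rand_rna <- function(n) {
  paste(sample(names(.code), n, replace = TRUE), collapse = "")
}

all_kmers <- function(k) {
  grid <- expand.grid(rep(list(names(.code)), k), stringsAsFactors = FALSE)
  do.call(paste0, grid)
}

# pairing predicates on integer codes
.ora_wc <- function(a, b) a + b == 5L
.ora_rel <- function(a, b) a + b == 5L | a + b == 7L

# Direct transcription of the seed-site motif definitions. w is an 8-nt
# window read 5'->3'; w[9 - j] opposes isomiR position j; w[8] opposes
# position 1 and only its identity (A or not) matters.
oracle_classify <- function(iso_seq, window) {
  s <- rna_codes(substr(iso_seq, 1, 8))
  w <- rna_codes(window)
  wc <- vapply(2:8, function(j) .ora_wc(s[j], w[9 - j]), logical(1))
  wc27 <- all(wc[1:6])
  a1 <- w[8] == 1L
  if (wc27 && wc[7]) return(if (a1) "8mer" else "7mer-m8")
  if (wc27) return(if (a1) "7mer-A1" else "6mer")
  rel <- vapply(2:7, function(j) .ora_rel(s[j], w[9 - j]), logical(1))
  if (sum(!rel) <= 1L) return("other")
  for (j in 2:7) {
    pp <- setdiff(2:7, j)
    ok <- TRUE
    for (k in 1:5) {
      if (!.ora_rel(s[pp[k]], w[8 - k])) {
        ok <- FALSE
        break
      }
    }
    if (ok) return("other")
  }
  "none"
}

# Brute-force sliding-window scan: TRUE when no 6-nt window of the
# transcript pairs the seed (isomiR positions 2-7) at all six positions
# under WC-or-wobble pairing. Window position k opposes isomiR position
# 8 - k, i.e. seed string position 7 - k.
oracle_is_nontarget <- function(iso_seq, tx_seq) {
  sd <- rna_codes(substr(iso_seq, 2, 7))
  tx <- rna_codes(tx_seq)
  L <- length(tx)
  if (L < 6L) return(TRUE)
  nw <- L - 5L
  ok <- rep(TRUE, nw)
  for (k in 1:6) {
    ok <- ok & .ora_rel(tx[k:(k + nw - 1L)], sd[7L - k])
  }
  !any(ok)
}

# Hypergeometric tail by explicit pmf summation over the support.
oracle_fisher <- function(m_tar, n_tar, m_nontar, n_nontar) {
  K <- m_tar + m_nontar
  N <- n_tar + n_nontar
  ks <- m_tar:min(n_tar, K)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n_tar - ks) - lchoose(N, n_tar)))
}

# O(m^2) step-up BH: q_(i) = min over j >= i of p_(j) * m / j, clipped.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    qs[i] <- min(ps[i:m] * m / (i:m), 1)
  }
  q <- numeric(m)
  q[o] <- qs
  q
}
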