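# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation.

# all n! permutations of 1:n, one per row
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# two-model least-squares F via explicit normal equations
naive_fstat <- function(y, covariate, df = 3) {
  X <- cbind(1, splines::ns(covariate, df = df))
  beta <- solve(crossprod(X), crossprod(X, y))
  rss1 <- sum((y - X %*% beta)^2)
  rss0 <- sum((y - mean(y))^2)
  d1 <- ncol(X)
  if (rss0 <= 1e-14 * max(sum(y^2), 1)) return(0)
  if (rss1 <= 0) return(Inf)
  ((rss0 - rss1) / (d1 - 1)) / (rss1 / (length(y) - d1))
}

# hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
enum_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)  # which universe elements belong to the set
  overlaps <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(overlaps >= k)
}

# window-by-window IUPAC scan over a character sequence
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

brute_count_motif <- function(seq, motif, both_strands = TRUE) {
  count_one <- function(seq, motif) {
    s <- strsplit(seq, "")[[1]]
    m <- strsplit(motif, "")[[1]]
    L <- length(m)
    if (length(s) < L) return(0)
    hits <- 0
    for (i in seq_len(length(s) - L + 1)) {
      ok <- TRUE
      for (j in seq_len(L)) {
        if (!(s[i + j - 1] %in% IUPAC_SETS[[m[j]]])) { ok <- FALSE; break }
      }
      if (ok) hits <- hits + 1
    }
    hits
  }
  revcomp <- function(x) paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN",
                                                   "TGCAYRSWMKVHDBN", x),
                                            "")[[1]]), collapse = "")
  n <- count_one(seq, motif)
  if (both_strands) n <- n + count_one(seq, revcomp(motif))
  n
}

# right-hand side of the maintenance-energy biomass balance, for deSolve
biomass_ode_rhs <- function(t, state, parms) {
  with(as.list(parms), {
    dCx <- Ysx_max * (D * (Cs_in - Cs) - ms_g * state[1])
    list(dCx)
  })
}

integrate_biomass_ode <- function(params, times) {
  out <- deSolve::lsoda(c(Cx = params$Cx0), times, biomass_ode_rhs,
                        c(Ysx_max = params$Ysx_max, D = params$D,
                          Cs_in = params$Cs_in, Cs = params$Cs,
                          ms_g = params$ms_g),
                        rtol = 1e-10, atol = 1e-12)
  out[, "Cx"]
}
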