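# Independent brute-force oracle for the entropy metrics, written straight
# from the definitions with plain loops. Deliberately shares no code with
# the package implementation.
#
# x: nonnegative vector; blocks: list of index vectors partitioning
# seq_along(x); base: logarithm base (exp(1) by default).
oracle_scores <- function(x, blocks, base = exp(1)) {
  lg <- function(v) log(v, base = base)
  S <- sum(x)
  p <- x / S
  E_T <- 0
  for (pi in p) if (pi > 0) E_T <- E_T - pi * lg(pi)
  r <- length(blocks)
  p_C <- numeric(r)
  E_C <- numeric(r)
  for (b in seq_len(r)) {
    xs <- x[blocks[[b]]]
    p_C[b] <- sum(xs) / S
    if (sum(xs) > 0) {
      q <- xs / sum(xs)
      for (qi in q) if (qi > 0) E_C[b] <- E_C[b] - qi * lg(qi)
    }
  }
  E_W <- sum(p_C * E_C)
  E_B_direct <- 0
  for (pc in p_C) if (pc > 0) E_B_direct <- E_B_direct - pc * lg(pc)
  if (E_T > 0 && E_W > 0) {
    Psi <- E_W / E_T
    psi <- p_C * E_C / E_W
    H <- 0
    for (ps in psi) if (ps > 0) H <- H - ps * lg(ps)
    zeta <- 1 - H / lg(r)
  } else {
    Psi <- zeta <- NA_real_
    psi <- rep(NA_real_, r)
  }
  list(E_T = E_T, E_B = E_T - E_W, E_B_direct = E_B_direct, E_W = E_W,
       p_C = p_C, E_C = E_C, Psi = Psi, psi = psi, zeta = zeta)
}

# Count vertex orderings of a regular r-gon up to rotation and reflection
# by exhaustive enumeration (feasible for r <= 6).
count_layouts_by_enumeration <- function(r) {
  canonical <- function(perm) {
    best <- NULL
    for (ref in 0:1) {
      p <- if (ref) rev(perm) else perm
      for (s in 0:(r - 1)) {
        q <- c(p[(s + 1):r], if (s > 0) p[1:s])
        key <- paste(q, collapse = ",")
        if (is.null(best) || key < best) best <- key
      }
    }
    best
  }
  gen <- function(avail, cur) {
    if (!length(avail)) return(list(cur))
    unlist(lapply(seq_along(avail), function(i) {
      gen(avail[-i], c(cur, avail[i]))
    }), recursive = FALSE)
  }
  length(unique(vapply(gen(seq_len(r), integer(0)), canonical,
                       character(1))))
}

# blocks list -> Partition (labels b1..br in list order)
blocks_to_partition <- function(blocks, n = max(unlist(blocks))) {
  a <- integer(n)
  for (b in seq_along(blocks)) a[blocks[[b]]] <- b
  partition(a, paste0("b", seq_along(blocks)))
}
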