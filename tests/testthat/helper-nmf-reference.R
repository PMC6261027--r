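# Straight-line reference implementation of the alternating
# multiplicative updates for the squared-Frobenius cost. Kept
# deliberately plain (explicit transposes and products, no shared code
# with the package) so it can serve as an independent oracle for the
# objective trace.
ref_nmf_trace <- function(PD, PR0, DR0, n_iter, eps = 1e-12) {
  PD <- as.matrix(PD)
  PR <- as.matrix(PR0)
  DR <- as.matrix(DR0)
  objective <- function(PR, DR) sum((PD - PR %*% t(DR))^2)
  trace <- numeric(n_iter + 1L)
  trace[1L] <- objective(PR, DR)
  for (it in seq_len(n_iter)) {
    PR <- PR * (PD %*% DR) / (PR %*% (t(DR) %*% DR) + eps)
    DR <- DR * (t(PD) %*% PR) / (DR %*% (t(PR) %*% PR) + eps)
    trace[it + 1L] <- objective(PR, DR)
  }
  trace
}

# Seeded uniform initialization shared between package and reference.
unif_init <- function(N, M, R, seed) {
  set.seed(seed)
  list(PR = matrix(runif(N * R), N, R),
       DR = matrix(runif(M * R), M, R))
}
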