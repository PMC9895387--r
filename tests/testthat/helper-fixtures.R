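# Shared fixtures, built once per test run. Everything is generated in code;
# sizes are kept small so single tests stay fast.

fx <- local({
  montage <- montage_1010()
  mesh <- cortical_mesh(2)                 # 162 vertices
  head <- sphere_head_model()
  lead <- build_sphere_leadfield(head, montage, mesh)
  atlas <- synthetic_atlas(mesh, 8)
  list(montage = montage, mesh = mesh, head = head, lead = lead,
       atlas = atlas)
})

## brute-force GFP of one map
gfp_oracle <- function(v) sqrt(mean((v - mean(v))^2))

## microstate-band preprocessing used throughout
ms_prep <- function(rec) rereference_average(bandpass_filter(rec, 2, 20))

## amplitude of a sinusoid buried in the middle of a filtered trace
mid_amplitude <- function(x) {
  n <- length(x)
  i <- seq(floor(n / 3), ceiling(2 * n / 3))
  (max(x[i]) - min(x[i])) / 2
}

## exhaustive best-GEV polarity-invariant 2-prototype model over all
## 2-partitions of <= 8 maps: prototypes are the partition eigenvectors and
## every map then counts its best prototype, matching the model's GEV
best_gev_k2_oracle <- function(maps, w) {
  n <- nrow(maps)
  Xn <- maps - rowMeans(maps)
  Xn <- Xn / sqrt(rowSums(Xn^2))
  w2 <- w^2
  best <- 0
  for (mask in 1:(2^n - 2)) {
    g1 <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    g2 <- setdiff(seq_len(n), g1)
    P <- t(vapply(list(g1, g2), function(g) {
      A <- Xn[g, , drop = FALSE]
      eigen(crossprod(A), symmetric = TRUE)$vectors[, 1]
    }, numeric(ncol(Xn))))
    cc2 <- apply((Xn %*% t(P))^2, 1, max)
    best <- max(best, sum(w2 * cc2) / sum(w2))
  }
  best
}

## independent textbook sums-of-squares oracle via stats::aov error strata
aov_oracle <- function(X) {
  n <- dim(X)[1]; a <- dim(X)[2]; b <- dim(X)[3]
  df <- data.frame(y = as.vector(X),
                   s = factor(rep(seq_len(n), a * b)),
                   A = factor(rep(rep(seq_len(a), each = n), b)),
                   B = factor(rep(seq_len(b), each = n * a)))
  fit <- summary(stats::aov(y ~ A * B + Error(s / (A * B)), data = df))
  get <- function(stratum, row) {
    tab <- fit[[stratum]][[1]]
    c(SS = tab[row, "Sum Sq"], df = tab[row, "Df"],
      F = if (nrow(tab) > 1 && row == 1) tab[1, "F value"] else NA)
  }
  list(A = get("Error: s:A", 1), A_err = get("Error: s:A", 2),
       B = get("Error: s:B", 1), B_err = get("Error: s:B", 2),
       AB = get("Error: s:A:B", 1), AB_err = get("Error: s:A:B", 2))
}

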