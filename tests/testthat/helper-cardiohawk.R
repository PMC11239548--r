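# Shared fixtures and independent oracles, all built in code.

sphere <- function(x) sum(x^2)
rastrigin <- function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))

# Small well-separated cohort for fast end-to-end tests.
tiny_cohort <- function(n = 120, seed = 1, ...) {
  generate_cohort(cohort_spec(n_total = n, n_healthy = n / 2, seed = seed, ...))
}

smoke_optimizer <- function(seed = 1)
  hho_config(population = 4, max_iterations = 3, variant = "lc_hhoa",
             patience = 2, seed = seed)

# Independent scalar recomputation of one GRU step (element loops only).
gru_step_oracle <- function(x, h, w) {
  d_h <- w$d_h
  out <- numeric(d_h)
  for (i in seq_len(d_h)) {
    z <- 1 / (1 + exp(-(sum(w$W_z[i, ] * x) + sum(w$U_z[i, ] * h) + w$b_z[i])))
    r <- 1 / (1 + exp(-(sum(w$W_r[i, ] * x) + sum(w$U_r[i, ] * h) + w$b_r[i])))
    rh <- numeric(d_h)
    for (j in seq_len(d_h)) rh[j] <- r_at(w, h, x, j)
    hc <- tanh(sum(w$W_h[i, ] * x) + sum(w$U_h[i, ] * (rh * h)) + w$b_h[i])
    out[i] <- (1 - z) * h[i] + z * hc
  }
  out
}
r_at <- function(w, h, x, j)
  1 / (1 + exp(-(sum(w$W_r[j, ] * x) + sum(w$U_r[j, ] * h) + w$b_r[j])))

# Double-loop softmax attention oracle.
attention_oracle <- function(H, p) {
  Q <- H %*% p$W_q; K <- H %*% p$W_k; V <- H %*% p$W_v
  Tn <- nrow(H)
  ctx <- matrix(0, Tn, p$d_k)
  for (i in seq_len(Tn)) {
    s <- numeric(Tn)
    for (j in seq_len(Tn)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(p$d_k)
    wgt <- exp(s - max(s)); wgt <- wgt / sum(wgt)
    for (k in seq_len(p$d_k)) ctx[i, k] <- sum(wgt * V[, k])
  }
  ctx
}

# Independent ridge solver via QR on the augmented system:
# min ||Y - H beta||^2 + (1/C) ||beta||^2.
ridge_oracle <- function(H, Y, C) {
  d <- ncol(H)
  Xa <- rbind(H, diag(d) / sqrt(C))
  Ya <- rbind(as.matrix(Y), matrix(0, d, ncol(as.matrix(Y))))
  qr.solve(Xa, Ya)
}

# Independent reference for the five measures from raw label vectors.
reference_metrics <- function(labels, pred) {
  tp <- sum(labels == "disease" & pred == "disease")
  fp <- sum(labels == "normal" & pred == "disease")
  tn <- sum(labels == "normal" & pred == "normal")
  fn <- sum(labels == "disease" & pred == "normal")
  sdiv <- function(a, b) if (b == 0) 0 else a / b
  pr <- sdiv(tp, tp + fp); rc <- sdiv(tp, tp + fn)
  list(accuracy = (tp + tn) / (tp + fp + tn + fn),
       recall = rc, specificity = sdiv(tn, tn + fp), precision = pr,
       f1 = if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc))
}

# Exact signed-rank enumeration: one-sided P(V >= v_obs) over all 2^n sign
# assignments (no ties assumed).
wilcoxon_enum_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% rk
  switch(alternative,
         greater = mean(v_all >= v_obs),
         less = mean(v_all <= v_obs),
         two.sided = min(1, 2 * min(mean(v_all >= v_obs), mean(v_all <= v_obs))))
}

sample_excess_kurtosis <- function(x) {
  mean((x - mean(x))^4) / mean((x - mean(x))^2)^2 - 3
}
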