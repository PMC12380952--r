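#!/usr/bin/env Rscript
# Step 3: test-retest reliability of the estimated parameters. Bivariate
# outliers are screened by Mahalanobis distance (p < 0.001), Pearson
# correlations are complemented by k-NN mutual information against the
# Gaussian reference curve, and the practice effect on the transformed
# stability index is tested with a paired t test.

library(levyflight)

pt <- read.csv("results/param_table.csv")
s1 <- pt[pt$session == 1, ]; s2 <- pt[pt$session == 2, ]
common <- intersect(s1$participant, s2$participant)

rows <- list()
for (p in c("a", "v1", "v2", "ndt", "alpha")) {
  ps <- paired_series(common, s1[[p]][match(common, s1$participant)],
                      s2[[p]][match(common, s2$participant)])
  scr <- mahalanobis_filter(ps, 0.001)
  rr <- retest_correlation(scr$kept)
  mi <- if (nrow(scr$kept) >= 50) knn_mi(scr$kept$x, scr$kept$y)$mi_mean
        else NA_real_
  rows[[p]] <- data.frame(
    parameter = p, r = rr$r, p_value = rr$p, stars = rr$stars, n = rr$n,
    excluded = length(scr$excluded_ids), mi_nats = mi,
    mi_gaussian_nats = if (abs(rr$r) < 1) gaussian_mi(rr$r) else NA)
}
# drift composites
vt1 <- s1$v1[match(common, s1$participant)] -
  s1$v2[match(common, s1$participant)]
vt2 <- s2$v1[match(common, s2$participant)] -
  s2$v2[match(common, s2$participant)]
rr <- retest_correlation(paired_series(common, vt1, vt2))
rows$v_total <- data.frame(parameter = "v_total", r = rr$r,
                           p_value = rr$p, stars = rr$stars, n = rr$n,
                           excluded = 0, mi_nats = NA,
                           mi_gaussian_nats = NA)
tab <- do.call(rbind, rows)
write.csv(tab, "results/retest_reliability.csv", row.names = FALSE)
cat("Test-retest reliability of estimated parameters:\n")
print(tab[, c("parameter", "r", "stars", "n")], row.names = FALSE)

# practice effect on the transformed stability index
a1 <- s1$alpha[match(common, s1$participant)]
a2 <- s2$alpha[match(common, s2$participant)]
tf <- stabilizing_transform(c(a1, a2), subtract_one = TRUE)
pe <- practice_effect(tf$values[seq_along(common)],
                      tf$values[length(common) + seq_along(common)])
cat(sprintf(paste0("\nPractice effect on transformed stability index: ",
                   "t(%d) = %.3f, p = %.4g, d = %.3f\n"),
            pe$dof, pe$t, pe$p, pe$cohen_d))
write.csv(data.frame(t = pe$t, dof = pe$dof, p = pe$p,
                     cohen_d = pe$cohen_d, mean_s1 = pe$mean_s1,
                     mean_s2 = pe$mean_s2),
          "results/practice_effect.csv", row.names = FALSE)
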