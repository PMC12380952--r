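#!/usr/bin/env Rscript
# Step 4: is the stability index's reliability intrinsic, or inherited from
# the boundary separation and non-decision time it correlates with?
# (a) Gradient-boosted regression predicts the session-2 stability index
#     from the session-1 index plus both sessions' a and ndt; permutation
#     importance says which predictors carry the signal.
# (b) The conditional-MI retention index: the share of the session-1 /
#     session-2 dependence that survives conditioning on (a_s1, a_s2) or
#     (ndt_s1, ndt_s2).

library(levyflight)

pt <- read.csv("results/param_table.csv")
s1 <- pt[pt$session == 1, ]; s2 <- pt[pt$session == 2, ]
common <- intersect(s1$participant, s2$participant)
g1 <- function(p) s1[[p]][match(common, s1$participant)]
g2 <- function(p) s2[[p]][match(common, s2$participant)]

features <- data.frame(alpha_s1 = g1("alpha"),
                       a_s1 = g1("a"), a_s2 = g2("a"),
                       ndt_s1 = g1("ndt"), ndt_s2 = g2("ndt"))
gbr <- gbr_reliability(features, g2("alpha"), seed = 7)
cat(sprintf("GBR: mean test R^2 = %.3f (sd %.3f), MAE %.3f, RMSE %.3f\n",
            gbr$cv_r2_mean, gbr$cv_r2_sd, gbr$mae_mean, gbr$rmse_mean))
print(as.data.frame(gbr$importances), row.names = FALSE)
write.csv(gbr$importances, "results/gbr_importances.csv",
          row.names = FALSE)

ret <- cmi_retention(g1("alpha"), g2("alpha"),
                     list(threshold = cbind(g1("a"), g2("a")),
                          ndt = cbind(g1("ndt"), g2("ndt"))))
cat(sprintf("\nUnconditional MI: %.3f nats\n", ret$mi_mean))
for (nm in names(ret$sets)) {
  cat(sprintf("Retention after conditioning on %s: %.2f%s\n", nm,
              ret$sets[[nm]]$retention_mean,
              if (ret$sets[[nm]]$unreliable) " (unreliable: MI near 0)"
              else ""))
}
write.csv(data.frame(conditioning = names(ret$sets),
                     retention = sapply(ret$sets, `[[`,
                                        "retention_mean"),
                     mi_nats = ret$mi_mean),
          "results/cmi_retention.csv", row.names = FALSE)
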