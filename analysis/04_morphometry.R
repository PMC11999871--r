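#!/usr/bin/env Rscript
# Morphometric estimators on synthetic annotations: exactness of the
# three-point opening angle, noise bias, and ablation-based lumen-state
# inference at the bulged and budded conditions.
library(cryptmorph)
dir.create("results", showWarnings = FALSE)

# exactness and noise bias of the opening angle
rows <- NULL
for (th in c(0.5, 1.5, 2.5)) {
  est <- vapply(1:1000, function(s) {
    tp <- gen_triplet(th, radius = 1, coord_sd = 0.01, seed = 20000 + s)
    g <- function(role) as.numeric(tp[tp$role == role, c("x", "y")])
    opening_angle(g("boundary1"), g("middle"), g("boundary2"))
  }, 0)
  rows <- rbind(rows, data.frame(
    theta_true = th, mean_est = mean(est), sd_est = sd(est),
    bias = mean(est) - th, se = sd(est) / sqrt(1000)))
}
write.csv(rows, "results/opening_angle_recovery.csv", row.names = FALSE)
cat("Opening-angle recovery under 1% coordinate noise:\n"); print(rows)

# whole-organoid annotations -> degree of opening
ann <- gen_triplets(24, theta_c_true = seq(0.4, 1.8, length.out = 24),
                    opening = 0.75, coord_sd = 0.3, seed = 7)
res <- angles_from_annotations(ann)
write.csv(res, "results/synthetic_morphometry.csv", row.names = FALSE)
cat(sprintf("\nMean degree of opening across %d synthetic organoids: %.3f (generating value 0.75)\n",
            nrow(res), mean(res$opening)))

# ablation-based lumen state at the two experimental conditions
ab_b <- gen_ablation(2.77, rel_sd = 0.15, n = 11, seed = 11)
ab_d <- gen_ablation(0.71, rel_sd = 0.15, n = 9, seed = 12)
inf_b <- infer_v(ab_b$v_pre, ab_b$v_post)
inf_d <- infer_v(ab_d$v_pre, ab_d$v_post)
out <- data.frame(condition = c("bulged", "budded"),
                  v_mean = c(attr(inf_b, "mean"), attr(inf_d, "mean")),
                  v_sd = c(attr(inf_b, "sd"), attr(inf_d, "sd")),
                  n = c(11, 9))
write.csv(out, "results/ablation_inference.csv", row.names = FALSE)
cat("\nInferred normalized lumen volumes from pre/post-ablation pairs:\n")
print(out)
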