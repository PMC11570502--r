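#!/usr/bin/env Rscript
# Stage 2 — recover the call-type repertoire.
#
# Clusters the calls on (duration, maximum frequency) with Partitioning
# Around Medoids, selects the number of clusters by mean silhouette over
# k = 2..10, labels the low-frequency cluster "A" and the high-frequency
# cluster "B", and writes the labeled calls and the silhouette curve.

suppressMessages(library(callgram))

calls <- read_calls("results/corpus/calls.csv")
st <- standardize_features(calls)
sel <- select_k(st$x, 2:10)
fit <- sel$fits$k2
calls <- label_clusters(fit, calls)

write.csv(sel$curve, "results/silhouette_curve.csv", row.names = FALSE)
out <- calls
names(out)[match(c("onset", "duration", "max_frequency"), names(out))] <-
  c("onset_s", "duration_s", "max_freq_khz")
write.csv(out, "results/calls_labeled.csv", row.names = FALSE)

cat("Silhouette curve (k: mean width):\n")
print(sel$curve, row.names = FALSE)
cat("Best k =", sel$best_k, "with mean silhouette",
    round(max(sel$curve$mean_silhouette), 3), "\n")
agree <- 100 * mean(calls$assigned_type == calls$true_type)
cat(sprintf("Agreement with generating call types: %.2f%% of %d calls\n",
            agree, nrow(calls)))
cat(sprintf("Type means: A %.2f kHz / %.3f s, B %.2f kHz / %.3f s\n",
            mean(calls$max_frequency[calls$assigned_type == "A"]),
            mean(calls$duration[calls$assigned_type == "A"]),
            mean(calls$max_frequency[calls$assigned_type == "B"]),
            mean(calls$duration[calls$assigned_type == "B"])))
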