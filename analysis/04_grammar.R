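#!/usr/bin/env Rscript
# Stage 4 — grammar analysis of the sequence corpus.
#
# Classifies every sequence into its pattern class, evaluates the three
# combinatorial rules (A-Dominance, A-Suffixation, B-Singularity), builds
# the prefix trie, and writes the repertoire summary, the annotated
# sequences and the trie in Graphviz DOT.

suppressMessages(library(callgram))

seqs <- read.csv("results/sequences.csv", stringsAsFactors = FALSE)
seqs$pattern <- as.character(classify_pattern(seqs$symbols))
seqs$initiation <- initiation(seqs$symbols)
seqs$termination <- termination_bigram(seqs$symbols)

cat("Combinatorial rules over", nrow(seqs), "sequences:\n")
print(check_rules(seqs$symbols))

rs <- repertoire_summary(seqs$symbols)
cat("\nRepertoire summary:\n")
print(rs)

trie <- build_trie(seqs$symbols)
export_trie_dot(trie, "results/trie.dot")
write.csv(seqs, "results/sequences_annotated.csv", row.names = FALSE)
jsonlite::write_json(unclass(rs), "results/repertoire_summary.json",
                     auto_unbox = TRUE, digits = NA)
cat("\nWritten: sequences_annotated.csv, repertoire_summary.json, trie.dot\n")
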