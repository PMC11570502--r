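# Prefix trie over call sequences. Nodes are nested lists: each node carries
# its symbol, the number of sequences passing through it, the number ending
# exactly there (the terminal marker), its depth (ordinal call position) and
# named children.

new_trie_node <- function(symbol, depth) {
  list(symbol = symbol, depth = depth, pass = 0L, terminal = 0L,
       children = list())
}

trie_insert <- function(node, chars, count) {
  node$pass <- node$pass + count
  if (!length(chars)) {
    node$terminal <- node$terminal + count
    return(node)
  }
  s <- chars[1]
  if (is.null(node$children[[s]]))
    node$children[[s]] <- new_trie_node(s, node$depth + 1L)
  node$children[[s]] <- trie_insert(node$children[[s]], chars[-1], count)
  node
}

#' Build the prefix trie of a sequence corpus
#'
#' One root-to-node path per distinct prefix; `pass` counts the sequences
#' running through a node and `terminal` the sequences ending exactly there,
#' so at every node `terminal + sum(children pass) = pass` and the terminal
#' counts over the whole trie sum to the corpus size.
#'
#' @param symbols character vector of sequence strings (length >= 2 each);
#'   an empty vector yields a root-only trie.
#' @return nested list of class `"callgram_trie"` (the root node).
#' @export
build_trie <- function(symbols) {
  root <- new_trie_node("root", 0L)
  if (length(symbols)) {
    check_symbols(symbols)
    tab <- table(symbols)
    for (i in seq_along(tab))
      root <- trie_insert(root, strsplit(names(tab)[i], "")[[1]],
                          as.integer(tab[[i]]))
  }
  class(root) <- "callgram_trie"
  root
}

# conservation law: terminal + sum(child passes) == pass at every node
trie_conserved <- function(node) {
  kids <- node$children
  here <- node$terminal + sum(vapply(kids, `[[`, 0L, "pass")) == node$pass
  here && all(vapply(kids, trie_conserved, TRUE))
}

trie_n_nodes <- function(node) {
  1L + sum(vapply(node$children, trie_n_nodes, 0L))
}

trie_terminal_total <- function(node) {
  node$terminal + sum(vapply(node$children, trie_terminal_total, 0L))
}

# leaves (childless nodes) whose terminal count is exactly one
trie_singleton_leaves <- function(node) {
  if (!length(node$children)) return(as.integer(node$terminal == 1L))
  sum(vapply(node$children, trie_singleton_leaves, 0L))
}

#' @export
print.callgram_trie <- function(x, ...) {
  cat("Sequence trie:", x$pass, "sequences,", trie_n_nodes(x), "nodes\n")
  invisible(x)
}

#' Export a trie to Graphviz DOT
#'
#' Writes the trie as a directed graph: call nodes labeled by symbol, ranked
#' by depth (ordinal call position), and one end marker per terminal node,
#' its edge labeled with the terminal count.
#'
#' @param trie a `"callgram_trie"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_trie_dot <- function(trie, path) {
  stopifnot(inherits(trie, "callgram_trie"))
  lines <- c("digraph trie {", "  rankdir=LR;",
             "  node [shape=circle];",
             "  n0 [label=\"root\", shape=box];")
  counter <- 1L
  walk <- function(node, id) {
    out <- character(0)
    if (node$terminal > 0) {
      tid <- sprintf("t%d", counter); counter <<- counter + 1L
      out <- c(out,
               sprintf("  %s [label=\"\\u22a3\", shape=plaintext];", tid),
               sprintf("  n%d -> %s [label=\"%d\"];", id, tid, node$terminal))
    }
    for (s in names(node$children)) {
      cid <- counter; counter <<- counter + 1L
      ch <- node$children[[s]]
      out <- c(out,
               sprintf("  n%d [label=\"%s\", rank=%d];", cid, s, ch$depth),
               sprintf("  n%d -> n%d [label=\"%d\"];", id, cid, ch$pass),
               walk(ch, cid))
    }
    out
  }
  lines <- c(lines, walk(trie, 0L), "}")
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write ", path, call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
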