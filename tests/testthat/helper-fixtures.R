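# Small file/graph builders shared across tests.

write_temp_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

records <- function(a, b, score) {
  data.frame(protein_a = a, protein_b = b, score = as.integer(score),
             stringsAsFactors = FALSE)
}

# A 7-node graph with two tied shortest paths between n1 and n4:
# n1-n2-n4 and n1-n3-n4, both of weight 400. The tie rule must pick
# the route through the lexicographically smaller predecessor.
tied_paths_graph <- function() {
  build_graph(records(
    a = c("n1", "n2", "n1", "n3", "n1", "n5", "n6"),
    b = c("n2", "n4", "n3", "n4", "n5", "n6", "n7"),
    score = c(800, 800, 800, 800, 700, 700, 700)
  ))
}
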