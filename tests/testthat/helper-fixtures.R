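# Shared fixture builders for the test suite. Everything is constructed in
# code; no binary fixtures.

# A minimal genome: one gene per supplied label, laid out as requested.
# `layout` rows: label, contig, start, end, strand.
make_genome <- function(mag_id, labels, cluster_id = mag_id,
                        contig = "c1", gap = 100L, width = 900L,
                        strand = "+", proteins = character(0)) {
  start <- seq(1L, by = width + gap, length.out = length(labels))
  genome_annotation(
    mag_id,
    data.frame(gene_id = sprintf("%s_g%02d", mag_id, seq_along(labels)),
               labels = labels, contig = contig, start = start,
               end = start + width - 1L, strand = strand,
               stringsAsFactors = FALSE),
    cluster_id = cluster_id, proteins = proteins)
}

# A genome from an explicit gene table (for operon/contig layouts).
make_genome_tab <- function(mag_id, tab, cluster_id = mag_id,
                            proteins = character(0)) {
  tab$gene_id <- sprintf("%s_g%02d", mag_id, seq_len(nrow(tab)))
  genome_annotation(mag_id, tab, cluster_id = cluster_id,
                    proteins = proteins)
}

# An ad-hoc pathway definition without touching the catalog.
make_pathway <- function(id, steps, carriers = character(0),
                         reaction_stoich = c(h2 = 1, hplus = -1,
                                             formate = -1, hco3 = 1,
                                             h2o = 0),
                         ledger = carrier_ledger(atp_gen = 1),
                         directionality = "catabolic_marker_present") {
  reaction_stoich <- reaction_stoich[reaction_stoich != 0]
  structure(list(id = id, name = id, substrate_class = "AA",
                 canonical = FALSE,
                 reaction = reaction(id, reaction_stoich, check = FALSE),
                 ledger = ledger, carriers_generated = carriers,
                 steps = steps, marker_steps = character(0),
                 directionality = directionality),
            class = "pathway_def")
}

# A cytochrome-like sequence with n CXXCH motifs, built independently of
# the generator.
make_cytochrome_seq <- function(n_motifs, length = 120) {
  s <- rep("A", length)
  starts <- round(seq(5, length - 5, length.out = n_motifs))
  for (st in starts) s[st:(st + 4)] <- c("C", "G", "G", "C", "H")
  paste(s, collapse = "")
}

# Independent reachability oracle: exhaustive enumeration of all simple
# paths from `from`, checking whether any reaches a sink. No igraph.
enumerate_reaches_sink <- function(edges, from, sinks) {
  if (length(edges) == 0) return(FALSE)
  reached <- FALSE
  walk <- function(node, visited) {
    if (node %in% sinks) { reached <<- TRUE; return(invisible()) }
    nxt <- edges$to[edges$from == node & !(edges$to %in% visited)]
    for (n in nxt) walk(n, c(visited, n))
  }
  walk(from, from)
  reached
}

# Bisection oracle for H2 thresholds: root of net_delta_g over ln(p).
bisect_h2 <- function(rxn, cond, atp, lower = 1e-30, upper = 1e30) {
  f <- function(lp) {
    cond$activities["h2"] <- exp(lp)
    net_delta_g(rxn, cond, atp)
  }
  exp(stats::uniroot(f, c(log(lower), log(upper)), tol = 1e-12)$root)
}
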