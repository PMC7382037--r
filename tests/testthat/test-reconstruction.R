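test_that("pathway completeness requires one gene per step", {
  catalog <- pathway_catalog()
  but <- catalog$butyrate_betaox
  full <- make_genome("m1", c("ctf", "bcd", "crt", "hbd", "thl", "ack"))
  res <- pathway_complete(full, but)
  expect_true(res$complete)
  expect_length(res$missing_steps, 0)
  expect_true(all(vapply(res$witness, length, 0L) == 1))

  # missing exactly one step is reported
  part <- make_genome("m2", c("ctf", "bcd", "crt", "hbd", "ack"))
  res2 <- pathway_complete(part, but)
  expect_false(res2$complete)
  expect_identical(res2$missing_steps, 5L)  # thiolase step

  # alternative labels satisfy a step ("pta" instead of "ack")
  alt <- make_genome("m3", c("ctf", "bcd", "crt", "hbd", "thl", "pta"))
  expect_true(pathway_complete(alt, but)$complete)
})

test_that("carrier re-oxidation needs transfer routes for every carrier", {
  # an AA pathway producing NADH and NADPH, genome encoding only a
  # ferredoxin-dependent hydrogenase: rejected without Rnf + Nfn
  aa <- make_pathway("aa_test", steps = list("ald"),
                     carriers = c("NADH", "NADPH"))
  ech_only <- make_genome_tab("m1", data.frame(
    labels = c("ald", "echA", "echB", "echC"), contig = "c1",
    start = c(1, 2001, 3101, 4201), end = c(900, 3000, 4100, 5200),
    strand = "+", stringsAsFactors = FALSE))
  expect_false(electron_balance(ech_only, aa)$balanced)

  with_rnf_nfn <- make_genome_tab("m2", data.frame(
    labels = c("ald", "echA", "echB", "echC",
               "rnfA", "rnfB", "rnfC", "rnfD", "rnfE", "rnfG",
               "nfnA", "nfnB"),
    contig = "c1", start = seq(1, by = 1100, length.out = 12),
    end = seq(1, by = 1100, length.out = 12) + 999,
    strand = "+", stringsAsFactors = FALSE))
  bal <- electron_balance(with_rnf_nfn, aa)
  expect_true(bal$balanced)
  expect_setequal(bal$routing$NADH, "h2_sink")
  expect_setequal(bal$routing$NADPH, "h2_sink")

  # pathway with no external carriers passes vacuously
  mcr_only <- make_genome("m3", "mcr")
  vac <- make_pathway("methano", steps = list("mcr"), carriers = character(0))
  expect_true(electron_balance(mcr_only, vac)$balanced)
})

test_that("reachability agrees with exhaustive path enumeration", {
  defs <- electron_transfer_defs()
  genomes <- list(
    make_genome("g1", c("rnfA", "rnfB", "rnfC", "rnfD", "rnfE", "rnfG",
                        "fdhA")),
    make_genome("g2", c("fixA", "fixB", "fdnG", "fdnH", "fdnI")),
    make_genome("g3", c("efdA", "efdB", "echA", "echB", "echC", "ndh")),
    make_genome("g4", c("nfnA", "nfnB", "hydA", "hydB", "hydC")),
    make_genome("g5", c("cydA", "cydB", "ndh", "fdhA"))
  )
  carriers <- c("NADH", "NADPH", "FdH2", "ETFH2", "quinol")
  for (g in genomes) {
    pw <- make_pathway("probe", steps = list(), carriers = carriers)
    bal <- electron_balance(g, pw, defs)
    # reconstruct the edge list independently from the definitions
    edges <- data.frame(from = character(0), to = character(0))
    for (nm in bal$present) {
      spec_edges <- if (nm %in% names(defs$complexes)) {
        defs$complexes[[nm]]$edges
      } else defs$singles[[nm]]$edges
      for (e in spec_edges) {
        edges <- rbind(edges, data.frame(from = e[[1]], to = e[[2]]))
      }
    }
    for (ca in carriers) {
      expect_identical(length(bal$routing[[ca]]) > 0,
                       enumerate_reaches_sink(edges, ca, defs$sinks),
                       info = paste(g$mag_id, ca))
    }
  }
})

test_that("complexes require operon co-localisation or split contig ends", {
  sub3 <- c("echA", "echB", "echC")
  # adjacent, same strand: present
  ok <- make_genome("m1", sub3, gap = 100L)
  expect_true(complex_present(ok, sub3))
  # scattered on three contigs: absent
  scat <- make_genome_tab("m2", data.frame(
    labels = sub3, contig = c("c1", "c2", "c3"),
    start = c(1, 1, 1), end = c(900, 900, 900), strand = "+",
    stringsAsFactors = FALSE))
  expect_false(complex_present(scat, sub3))
  # gap beyond the operon limit: absent
  gap <- make_genome("m3", sub3, gap = 2000L)
  expect_false(complex_present(gap, sub3))
  # opposite strands: absent
  str <- make_genome_tab("m4", data.frame(
    labels = sub3, contig = "c1", start = c(1, 1101, 2201),
    end = c(1000, 2100, 3200), strand = c("+", "-", "+"),
    stringsAsFactors = FALSE))
  expect_false(complex_present(str, sub3))
  # split across two contig ends: subunits 1-2 end contig A, 3 starts B
  split2 <- make_genome_tab("m5", data.frame(
    labels = c("hk_1", "echA", "echB", "echC", "hk_2"),
    contig = c("cA", "cA", "cA", "cB", "cB"),
    start = c(1, 5001, 6101, 1, 1101),
    end = c(900, 6000, 7100, 1000, 2100),
    strand = "+", stringsAsFactors = FALSE))
  expect_true(complex_present(split2, sub3))
  # interior placement on the second contig breaks the split-operon rule
  interior <- make_genome_tab("m6", data.frame(
    labels = c("hk_1", "echA", "echB", "hk_2", "echC", "hk_3"),
    contig = c("cA", "cA", "cA", "cB", "cB", "cB"),
    start = c(1, 5001, 6101, 1, 5001, 9001),
    end = c(900, 6000, 7100, 1000, 6000, 10000),
    strand = "+", stringsAsFactors = FALSE))
  expect_false(complex_present(interior, sub3))
})

test_that("conductive pilin rule checks fraction and distribution", {
  # 5 aromatics in 100 residues: fraction below 9%
  s5 <- paste(replace(rep("A", 100), c(10, 30, 50, 70, 90), "F"),
              collapse = "")
  expect_false(conductive_pili(s5))
  # 10 aromatics spread one per 10 residues: accepted
  expect_true(conductive_pili(make_pilin(100, 0.10, clustered = FALSE)))
  # 10 aromatics packed into the first window: rejected
  expect_false(conductive_pili(make_pilin(100, 0.10, clustered = TRUE)))
  # case-invariant
  p <- make_pilin(100, 0.12)
  expect_identical(conductive_pili(tolower(p)), conductive_pili(p))
  expect_error(conductive_pili(""), "empty")
})

test_that("multiheme cytochrome rule combines motifs and localization", {
  s4 <- make_cytochrome_seq(4)
  expect_true(multiheme_cytochrome(s4, "extracellular"))
  expect_true(multiheme_cytochrome(s4, "membrane"))
  expect_false(multiheme_cytochrome(s4, "other"))
  s1 <- make_cytochrome_seq(1)
  expect_false(multiheme_cytochrome(s1, "membrane"))
  expect_true(multiheme_cytochrome(tolower(s4), "membrane"))
  # overlap-aware motif counting: CAACHXXCAACH has two motifs
  expect_true(multiheme_cytochrome("AACAACHAACAACHAA", "membrane"))
})

test_that("species clustering is single-linkage at the 0.05 cutoff", {
  d <- data.frame(mag1 = c("a", "b", "a"), mag2 = c("b", "c", "c"),
                  distance = c(0.04, 0.04, 0.2))
  cl <- cluster_species(d)
  # chain a-b-c merges through b despite d(a, c) = 0.2
  expect_identical(unname(cl["a"]), unname(cl["c"]))
  expect_identical(unname(cl["a"]), "a")  # lexicographic smallest labels

  d2 <- data.frame(mag1 = "x", mag2 = "y", distance = 0.06)
  cl2 <- cluster_species(d2)
  expect_false(cl2[["x"]] == cl2[["y"]])

  # matrix input agrees with long input
  m <- matrix(c(0, 0.04, 0.2, 0.04, 0, 0.04, 0.2, 0.04, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_identical(cluster_species(m), cl)
  expect_error(cluster_species(data.frame(mag1 = "a", mag2 = "b",
                                          distance = 1.2)), "0, 1")
})

test_that("capacity criteria reject unbalanced, endergonic and ambiguous calls", {
  catalog <- pathway_catalog()
  # planted syntroph: butyrate pathway, formate-only electron disposal
  syn <- make_genome("syn", c("ctf", "bcd", "crt", "hbd", "thl", "ack",
                              "rnfA", "rnfB", "rnfC", "rnfD", "rnfE", "rnfG",
                              "fdhA", "fixA", "fixB", "fdnG", "fdnH", "fdnI"))
  call <- capacity_predict(syn, catalog$butyrate_betaox)
  expect_true(call$capacity)
  bal <- electron_balance(syn, catalog$butyrate_betaox)
  expect_setequal(bal$routing$ETFH2, "formate_sink")
  expect_false("h2_sink" %in% unlist(bal$routing))

  # same genes without the transfer enzymes: carrier not re-oxidised
  bare <- make_genome("bare", c("ctf", "bcd", "crt", "hbd", "thl", "ack"))
  call2 <- capacity_predict(bare, catalog$butyrate_betaox)
  expect_false(call2$capacity)
  expect_match(call2$reason, "not re-oxidized")

  # endergonic under default conditions: rejected with the reason recorded
  leu_genome <- make_genome("leu", c("bat", "vor", "ptb", "hydA", "hydB",
                                     "hydC"))
  call3 <- capacity_predict(leu_genome, catalog$leucine_ox)
  expect_false(call3$capacity)
  expect_match(call3$reason, "not exergonic")

  # ambiguous directionality is flagged, never silently asserted
  ala_genome <- make_genome("ala", c("ald", "por", "pta", "hydA", "hydB",
                                     "hydC"))
  call4 <- capacity_predict(ala_genome, catalog$alanine_ox)
  expect_false(call4$capacity)
  expect_true(call4$ambiguous)
})

test_that("cluster capacities are the union of member-MAG capacities", {
  com <- generate_community(community_spec(seed = 11, dropout = 0.25))
  caps <- capacity_matrix(com$genomes, localizations = com$localizations)
  pm <- caps$per_mag
  for (cl in unique(pm$cluster_id)) {
    member_union <- unique(pm$pathway[pm$cluster_id == cl & pm$capacity])
    # every member MAG's capacity set is contained in the union
    for (mag in unique(pm$mag_id[pm$cluster_id == cl])) {
      mine <- pm$pathway[pm$mag_id == mag & pm$capacity]
      expect_true(all(mine %in% member_union))
    }
    cl_row <- caps$cluster[caps$cluster$cluster_id == cl, ]
    n_classes <- with(cl_row, n_sugar + n_aa_hs + n_aa_ht + n_fa)
    expect_lte(n_classes, length(member_union))
  }
})
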