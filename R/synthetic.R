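# Reactor panel mirroring a multi-plant digester survey: nine reactors
# spanning sub-mesophilic to thermophilic operation, triplicate
# metatranscriptomes each.
DEFAULT_REACTOR_TEMPS <- c(R1 = 25, R2 = 35, R3 = 35, R4 = 35, R5 = 38,
                           R6 = 40, R7 = 40, R8 = 53, R9 = 55)

#' Construct a pilin test sequence
#'
#' Builds a protein sequence of the requested length and aromatic
#' fraction. With `clustered = FALSE` aromatics are spread evenly along
#' the sequence; with `clustered = TRUE` they are packed into the first
#' 20-residue window so that the distribution criterion of
#' [conductive_pili()] must reject the sequence.
#'
#' @param length Sequence length (>= 20).
#' @param aromatic_fraction Target fraction of aromatic residues.
#' @param clustered Pack all aromatics into the first window.
#' @return A protein sequence string.
#' @export
#' @examples
#' conductive_pili(make_pilin(100, 0.10))        # TRUE
#' conductive_pili(make_pilin(100, 0.10, TRUE))  # FALSE
make_pilin <- function(length, aromatic_fraction, clustered = FALSE) {
  stopifnot(length >= PILIN_WINDOW)
  n_arom <- round(length * aromatic_fraction)
  if (n_arom > length || (clustered && n_arom > PILIN_WINDOW)) {
    stop("infeasible aromatic fraction for this length")
  }
  seqv <- rep("A", length)
  if (n_arom > 0) {
    pos <- if (clustered) {
      seq_len(n_arom)
    } else {
      round(seq(1, length, length.out = n_arom + 2)[2:(n_arom + 1)])
    }
    seqv[unique(pos)] <- rep(c("F", "Y", "W"), length.out = length(unique(pos)))
  }
  paste(seqv, collapse = "")
}

# A multiheme c-type cytochrome stand-in with n CXXCH motifs.
make_cytochrome <- function(n_motifs = 4, length = 120) {
  body <- rep("A", length)
  starts <- round(seq(5, length - 5, length.out = n_motifs))
  s <- paste(body, collapse = "")
  for (st in starts) substr(s, st, st + 4) <- "CAACH"
  s
}

#' Specify a synthetic community
#'
#' The generator's defaults emulate the study design the package is built
#' around: nine reactors (25-55 C) sampled in triplicate, niches planted
#' from the template set, triplicate log-normal expression noise
#' (sigma = 0.5) and optional gene dropout.
#'
#' @param seed Integer seed; fully determines the output.
#' @param reactors Named numeric vector of reactor temperatures (C).
#' @param noise_sigma Log-normal sigma of expression noise.
#' @param dropout Probability of deleting any single pathway/hydrolase
#'   gene from a genome (0 = faithful genomes).
#' @param total_reads Reads per reactor metatranscriptome.
#' @return Object of class `community_spec`.
#' @export
community_spec <- function(seed = 1, reactors = DEFAULT_REACTOR_TEMPS,
                           noise_sigma = 0.5, dropout = 0,
                           total_reads = 1e6) {
  stopifnot(dropout >= 0, dropout < 1, noise_sigma >= 0)
  structure(list(seed = as.integer(seed), reactors = reactors,
                 noise_sigma = noise_sigma, dropout = dropout,
                 total_reads = total_reads, niches = default_niches()),
            class = "community_spec")
}

# Niche templates: pathways planted, hallmark electron-transfer enzymes,
# hydrolase families, domain, and relative abundance per reactor.
# Abundances are normalised per reactor at generation time.
default_niches <- function() {
  list(
    hyd1 = list(template = "hydrolytic_HS_HT_coupler", domain = "bacteria",
                n_mags = 2,
                pathways = c("isoleucine_ox", "glutamine_ox", "glucose_ferm"),
                enzymes = c("hyd_fefe_bif", "rnf", "nfn"),
                n_protease = 6, n_gh = 5, n_lipase = 1,
                abundance = c(22, 22, 22, 22, 20, 20, 20, 16, 16)),
    hyd2 = list(template = "hydrolytic_HS_HT_coupler", domain = "bacteria",
                n_mags = 1,
                pathways = c("glycine_ox", "asparagine_ox"),
                enzymes = c("hyd_fefe_bif", "rnf"),
                n_protease = 4, n_gh = 4, n_lipase = 0,
                abundance = c(9, 9, 9, 9, 8, 8, 8, 10, 10)),
    syn_fo = list(template = "formate_only_FA_syntroph", domain = "bacteria",
                  n_mags = 2,
                  pathways = c("butyrate_betaox"),
                  enzymes = c("rnf", "fix", "fdh_n", "fdh_h"),
                  n_protease = 0, n_gh = 0, n_lipase = 0,
                  abundance = c(8, 8, 8, 8, 7, 7, 7, 0, 0)),
    syn_o2 = list(template = "o2_respiring_anaerobe", domain = "bacteria",
                  n_mags = 1,
                  pathways = c("butyrate_betaox", "isovalerate_carbox"),
                  enzymes = c("rnf", "fix", "fdh_h", "bd_oxidase", "ndh"),
                  n_protease = 0, n_gh = 0, n_lipase = 0,
                  abundance = c(6, 6, 6, 6, 6, 6, 6, 6, 6)),
    diet = list(template = "DIET_electrogen", domain = "bacteria",
                n_mags = 1,
                pathways = c("propionate_mmc"),
                enzymes = c("rnf", "fix", "fdh_n", "mhc_eet", "pilin"),
                n_protease = 0, n_gh = 0, n_lipase = 0,
                abundance = c(5, 5, 5, 5, 5, 5, 5, 5, 5)),
    ht = list(template = "HT_fermenter", domain = "bacteria",
              n_mags = 1,
              pathways = c("glucose_ferm"),
              enzymes = c("hyd_fefe_bif", "rnf"),
              n_protease = 1, n_gh = 2, n_lipase = 0,
              abundance = c(30, 30, 30, 30, 33, 33, 33, 40, 40)),
    aceto = list(template = "tripartite_acetoclast", domain = "archaea",
                 n_mags = 1,
                 pathways = c("methanogenesis_acetate", "methanogenesis_formate"),
                 enzymes = c("mhc_eet"),
                 n_protease = 0, n_gh = 0, n_lipase = 0,
                 abundance = c(10, 10, 10, 10, 11, 11, 11, 18, 18)),
    methyl = list(template = "methyl_reducing_methanogen", domain = "archaea",
                  n_mags = 1,
                  pathways = c("methanogenesis_methyl"),
                  enzymes = character(0),
                  n_protease = 0, n_gh = 0, n_lipase = 0,
                  abundance = c(5, 5, 5, 5, 5, 5, 5, 0, 0)),
    residual = list(template = "inactive_residual", domain = "bacteria",
                    n_mags = 1,
                    pathways = c("glucose_ferm"),
                    enzymes = c("hyd_fefe_bif"),
                    n_protease = 1, n_gh = 1, n_lipase = 0,
                    abundance = c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2))
  )
}

# Expand an enzyme name to the genes that must be planted for it.
.enzyme_genes <- function(enzyme, defs) {
  if (enzyme == "pilin") return("pilA")
  if (enzyme %in% names(defs$complexes)) {
    return(unlist(defs$complexes[[enzyme]]$subunits))
  }
  if (enzyme %in% names(defs$singles)) return(defs$singles[[enzyme]]$gene)
  stop("unknown enzyme in niche definition: ", enzyme)
}

#' Generate a synthetic community
#'
#' Deterministically (given the spec seed) builds genomes with planted
#' pathways and hallmark genes, pairwise MAG distances, protein sequences
#' for the sequence-rule classifiers, triplicate expression tables per
#' reactor with log-normal noise, per-cluster read counts, and a
#' ground-truth ledger of every planted capacity and expected
#' activity/consistency call.
#'
#' @param spec A [community_spec()].
#' @param catalog Pathway catalog used for the ortholog vocabulary.
#' @param defs Electron-transfer definitions.
#' @return List: `genomes`, `localizations`, `distances`, `expression`
#'   ([expression_set()]), `read_counts`, `domain`, `truth`, `spec`.
#' @export
#' @examples
#' com <- generate_community(community_spec(seed = 42))
#' names(com)
generate_community <- function(spec, catalog = pathway_catalog(),
                               defs = electron_transfer_defs()) {
  stopifnot(inherits(spec, "community_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  reactors <- names(spec$reactors)
  n_r <- length(reactors)
  niches <- spec$niches
  ab <- do.call(rbind, lapply(niches, `[[`, "abundance"))
  if (ncol(ab) != n_r) stop("niche abundances must cover every reactor")
  ab <- sweep(ab, 2, colSums(ab), "/")   # proportions per reactor sum to 1
  dimnames(ab) <- list(names(niches), reactors)

  genomes <- list()
  localizations <- character(0)
  truth_rows <- list()
  mag_niche <- character(0)

  for (ni in names(niches)) {
    nd <- niches[[ni]]
    for (k in seq_len(nd$n_mags)) {
      mag_id <- sprintf("%s_m%d", ni, k)
      mag_niche[mag_id] <- ni
      gene_rows <- list()
      proteins <- character(0)
      gi <- 0L
      add_gene <- function(labels, contig, start, end, strand) {
        gi <<- gi + 1L
        gene_rows[[gi]] <<- data.frame(
          gene_id = sprintf("%s_g%03d", mag_id, gi),
          labels = I(list(labels)), contig = contig, start = start,
          end = end, strand = strand, stringsAsFactors = FALSE)
        sprintf("%s_g%03d", mag_id, gi)
      }
      pos <- 1L
      # pathway step genes, scattered on the main contig
      step_labels <- unique(unlist(lapply(nd$pathways, function(pw) {
        vapply(catalog[[pw]]$steps, `[[`, "", 1)
      })))
      if (spec$dropout > 0) {
        step_labels <- step_labels[stats::runif(length(step_labels)) >=
                                     spec$dropout]
      }
      for (lb in step_labels) {
        add_gene(lb, "c1", pos, pos + 899L, "+")
        pos <- pos + 2500L
      }
      # hallmark electron-transfer enzymes; complexes as tight operons
      for (en in nd$enzymes) {
        genes <- .enzyme_genes(en, defs)
        if (length(genes) > 1) {
          for (g in genes) {
            gid <- add_gene(g, "c2", pos, pos + 999L, "+")
            pos <- pos + 1100L   # gap 100 bp within the operon
          }
          pos <- pos + 5000L
        } else {
          gid <- add_gene(genes, "c2", pos, pos + 999L, "+")
          pos <- pos + 3000L
          if (en == "pilin") {
            proteins[gid] <- make_pilin(100, 0.10, clustered = FALSE)
          }
          if (en == "mhc_eet") {
            proteins[gid] <- make_cytochrome(4)
            localizations[gid] <- "membrane"
          }
        }
      }
      # hydrolase families
      hyd <- c(if (nd$n_protease > 0)
                 sprintf("protease:S%02d", seq_len(nd$n_protease)),
               if (nd$n_gh > 0) sprintf("gh:GH%02d", seq_len(nd$n_gh)),
               if (nd$n_lipase > 0) sprintf("lipase:abH%02d",
                                            seq_len(nd$n_lipase)))
      if (spec$dropout > 0 && length(hyd) > 0) {
        hyd <- hyd[stats::runif(length(hyd)) >= spec$dropout]
      }
      for (lb in hyd) {
        add_gene(lb, "c3", pos, pos + 1199L, "+")
        pos <- pos + 2000L
      }
      # housekeeping background (a fifth stay silent in any one sample)
      for (j in seq_len(40)) {
        add_gene(sprintf("hk_%03d", j), "c4", pos, pos + 999L, "+")
        pos <- pos + 1500L
      }
      genomes[[mag_id]] <- genome_annotation(
        mag_id, do.call(rbind, gene_rows), cluster_id = ni,
        proteins = proteins)
    }
  }

  # pairwise distances: tight within clusters, distant between
  mags <- names(genomes)
  dist_rows <- list()
  for (i in seq_along(mags)) for (j in seq_len(i - 1L)) {
    same <- mag_niche[mags[i]] == mag_niche[mags[j]]
    d <- if (same) stats::runif(1, 0.01, 0.04) else stats::runif(1, 0.1, 0.6)
    dist_rows[[length(dist_rows) + 1]] <-
      data.frame(mag1 = mags[j], mag2 = mags[i], distance = d,
                 stringsAsFactors = FALSE)
  }
  distances <- do.call(rbind, dist_rows)

  # expression: triplicates per reactor; niche genes at a high baseline in
  # reactors where the niche is planted; housekeeping at baseline 1 with
  # stochastic silencing; all scaled by log-normal noise
  expr_rows <- list()
  for (rx in reactors) {
    for (rep_i in 1:3) {
      for (mag_id in mags) {
        ni <- mag_niche[mag_id]
        on <- ab[ni, rx] > 0
        g <- genomes[[mag_id]]$genes
        is_hk <- vapply(g$labels, function(l) startsWith(l[1], "hk_"),
                        logical(1))
        base <- ifelse(is_hk, 10, 50)
        silent <- is_hk & stats::runif(nrow(g)) < 0.2
        rpkm <- base * stats::rlnorm(nrow(g), 0, spec$noise_sigma)
        rpkm[silent] <- 0
        if (!on) rpkm[] <- 0   # niche absent from this reactor
        expr_rows[[length(expr_rows) + 1]] <- data.frame(
          reactor_id = rx, replicate_id = sprintf("%s_rep%d", rx, rep_i),
          gene_id = g$gene_id, rpkm = rpkm, stringsAsFactors = FALSE)
      }
    }
  }
  expression <- expression_set(do.call(rbind, expr_rows))

  # read counts per cluster per reactor (multinomial around abundances)
  rc_rows <- list()
  for (rx in reactors) {
    counts <- stats::rmultinom(1, spec$total_reads, ab[, rx])[, 1]
    rc_rows[[length(rc_rows) + 1]] <- data.frame(
      cluster_id = names(niches), reactor_id = rx, reads = counts,
      stringsAsFactors = FALSE)
  }
  read_counts <- do.call(rbind, rc_rows)

  domain <- vapply(niches, `[[`, "", "domain")

  # ground truth: planted capacities and expected activity calls
  thresholds <- c(bacteria = ACTIVE_THRESHOLD_BACTERIA,
                  archaea = ACTIVE_THRESHOLD_ARCHAEA)
  for (ni in names(niches)) {
    nd <- niches[[ni]]
    pct <- 100 * ab[ni, ]
    expect_active <- max(pct) >= thresholds[[nd$domain]]
    for (pw in nd$pathways) {
      ambiguous <- identical(catalog[[pw]]$directionality, "ambiguous")
      qual <- pct >= ECM_QUALIFY_FRACTION
      on <- ab[ni, ] > 0
      ecm <- if (!any(qual)) NA else mean(on[qual]) >= ECM_CONSISTENCY
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        cluster_id = ni, pathway = pw, template = nd$template,
        capacity = !ambiguous, ambiguous = ambiguous,
        cluster_active = expect_active,
        active_reactors = paste(reactors[on], collapse = ","),
        ecm50 = ecm, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth_rows)

  list(genomes = genomes, localizations = localizations,
       distances = distances, expression = expression,
       read_counts = read_counts, domain = domain, truth = truth,
       abundance = ab, spec = spec)
}
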