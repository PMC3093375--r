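# Synthetic barcode-data generator.
#
# Emulates the statistical structure a COI diversity assessment assumes:
# a family -> genus -> species -> individual hierarchy with rank-scaled
# divergences, transition-biased codon-aware sequence evolution with
# family-specific third-position GC, and injectable taxonomic anomalies
# (cryptic splits, haplotype-sharing species pairs, numt copies, sampling
# imbalance) with ground-truth labels for parameter-recovery testing.
#
# Substitution model: K80-style transition bias with position-class
# stationary frequencies (an HKY-type model). Third-position frequencies
# are family-specific, so family GC targets are stationary at every depth;
# with uniform frequencies the model reduces exactly to K80, the generative
# twin of the K2P estimator. Rates are normalized to one expected
# substitution per site per unit branch length, uniformly across sites, so
# tree path lengths are directly comparable to K2P estimates.

# Position-class stationary compositions (fractions). Positions 1 and 2 are
# fixed at COI-like values (GC1 ~ 0.51, GC2 ~ 0.43); position 3 is set per
# family from its GC3 target g.
PI_POS1 <- c(A = 0.25, C = 0.26, G = 0.25, T = 0.24)
PI_POS2 <- c(A = 0.16, C = 0.25, G = 0.18, T = 0.41)

pi_pos3 <- function(gc3) {
  c(A = 0.55 * (1 - gc3), C = 0.55 * gc3, G = 0.45 * gc3,
    T = 0.45 * (1 - gc3))
}

# HKY rate-ratio giving an expected transition/transversion COUNT ratio R
# at stationarity: R = kappa * (piA piG + piC piT) / ((piA+piG)(piC+piT)).
hky_rate_ratio <- function(pi, R) {
  R * (pi[["A"]] + pi[["G"]]) * (pi[["C"]] + pi[["T"]]) /
    (pi[["A"]] * pi[["G"]] + pi[["C"]] * pi[["T"]])
}

# One substitution "machine" per position class: normalized HKY generator
# plus a transition-probability function P(t) via eigendecomposition.
hky_machine <- function(pi, R) {
  pi <- pi[BASES]
  k <- hky_rate_ratio(pi, R)
  is_ts <- function(i, j) (i + j) %in% c(4L, 6L)  # {A,G}=1,3; {C,T}=2,4
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (i in 1:4) for (j in 1:4) if (i != j) {
    Q[i, j] <- pi[j] * if (is_ts(i, j)) k else 1
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  eg <- eigen(Q)
  Vinv <- solve(eg$vectors)
  Pfun <- function(t) {
    M <- Re(eg$vectors %*% diag(exp(eg$values * t)) %*% Vinv)
    M[M < 0] <- 0
    M / rowSums(M)
  }
  list(pi = pi, P = Pfun)
}

#' Simulation specification
#'
#' Parameters of the synthetic barcode generator. Rank divergence targets
#' are expected pairwise path lengths (fractions): conspecific pairs d_S,
#' congeneric d_G, confamilial d_F, interfamilial d_O; defaults follow the
#' order-level K2P means typical of decapod COI surveys (0.5\%, 15.5\%,
#' 22.3\%, 26.1\%).
#'
#' @param n_families,genera_per_family,species_per_genus taxonomy shape
#' @param records_per_species records per species; a scalar or a vector
#'   recycled across species
#' @param d_S,d_G,d_F,d_O rank divergence targets, 0 < d_S < d_G < d_F < d_O
#' @param kappa expected transition/transversion count ratio of the
#'   substitution process (default 2)
#' @param gc3_targets per-family third-position GC targets (fractions);
#'   default evenly spaced on [0.08, 0.32], echoing the spread observed
#'   across decapod families
#' @param sequence_length bases, a multiple of 3, at least 300 (default 657)
#' @param jitter_sd sigma of the multiplicative log-normal jitter applied
#'   to node heights (default 0.2)
#' @param p_cryptic per-species probability of an injected deep
#'   intraspecific split
#' @param p_merge per-genus probability of an injected haplotype-sharing
#'   (non-monophyletic) species pair
#' @param p_numt per-record probability of an injected nuclear pseudogene
#'   copy (GC3 shifted down 8 points plus one frameshifting deletion)
#' @param imbalance sampling-imbalance factor: one species' record count is
#'   multiplied by this factor with extra, more divergent records (1 =
#'   balanced)
#' @return A \code{sim_spec} list.
#' @export
sim_spec <- function(n_families = 5, genera_per_family = 2,
                     species_per_genus = 3, records_per_species = 5,
                     d_S = 0.005, d_G = 0.155, d_F = 0.223, d_O = 0.261,
                     kappa = 2, gc3_targets = NULL, sequence_length = 657,
                     jitter_sd = 0.2, p_cryptic = 0.027, p_merge = 0.10,
                     p_numt = 0.01, imbalance = 1) {
  stopifnot(d_S > 0, d_S < d_G, d_G < d_F, d_F < d_O,
            sequence_length >= 300, sequence_length %% 3 == 0,
            p_cryptic >= 0, p_cryptic <= 1, p_merge >= 0, p_merge <= 1,
            p_numt >= 0, p_numt <= 1, imbalance >= 1)
  if (is.null(gc3_targets)) {
    gc3_targets <- if (n_families == 1L) 0.20 else
      seq(0.08, 0.32, length.out = n_families)
  }
  gc3_targets <- rep_len(gc3_targets, n_families)
  structure(list(n_families = n_families,
                 genera_per_family = genera_per_family,
                 species_per_genus = species_per_genus,
                 records_per_species = records_per_species,
                 d_S = d_S, d_G = d_G, d_F = d_F, d_O = d_O,
                 kappa = kappa, gc3_targets = gc3_targets,
                 sequence_length = sequence_length, jitter_sd = jitter_sd,
                 p_cryptic = p_cryptic, p_merge = p_merge, p_numt = p_numt,
                 imbalance = imbalance),
            class = "sim_spec")
}

#' Simulate the generating taxonomy tree
#'
#' An ultrametric-style nested tree: individuals of a species coalesce at
#' height d_S/2, species of a genus at d_G/2, genera of a family at d_F/2
#' and families at d_O/2, each node height multiplied by log-normal jitter
#' (sigma = \code{jitter_sd}) and clamped above its children. Expected
#' pairwise path lengths therefore match the rank targets.
#'
#' @param spec a \code{\link{sim_spec}}
#' @param seed integer seed
#' @return List with \code{tree} (a \code{phylo}; tips are record ids,
#'   internal nodes labelled with their taxon code) and \code{taxonomy}
#'   (data frame record_id/species/genus/family).
#' @export
simulate_taxonomy_tree <- function(spec, seed) {
  with_rng(seed, {
    jit <- function(h) h * exp(stats::rnorm(1, 0, spec$jitter_sd))
    hS <- spec$d_S / 2; hG <- spec$d_G / 2
    hF <- spec$d_F / 2; hO <- spec$d_O / 2
    n_species_total <- spec$n_families * spec$genera_per_family *
      spec$species_per_genus
    k_per_species <- rep_len(spec$records_per_species, n_species_total)
    tax <- list()
    fam_frags <- character(0); fam_heights <- numeric(0)
    sp_counter <- 0L
    for (f in seq_len(spec$n_families)) {
      fam <- sprintf("F%02d", f)
      gen_frags <- character(0); gen_heights <- numeric(0)
      for (g in seq_len(spec$genera_per_family)) {
        gen <- sprintf("%sG%02d", fam, g)
        sp_frags <- character(0); sp_heights <- numeric(0)
        for (s in seq_len(spec$species_per_genus)) {
          sp_counter <- sp_counter + 1L
          spc <- sprintf("%sS%02d", gen, s)
          k <- k_per_species[sp_counter]
          recs <- sprintf("%sR%02d", spc, seq_len(k))
          tax[[length(tax) + 1L]] <-
            data.frame(record_id = recs, species = spc, genus = gen,
                       family = fam, stringsAsFactors = FALSE)
          if (k == 1L) {
            sp_frags <- c(sp_frags, recs)
            sp_heights <- c(sp_heights, 0)
          } else {
            h <- jit(hS)
            frag <- sprintf("(%s)%s",
                            paste(sprintf("%s:%s", recs, fmt_len(h)),
                                  collapse = ","), spc)
            sp_frags <- c(sp_frags, frag)
            sp_heights <- c(sp_heights, h)
          }
        }
        if (length(sp_frags) == 1L) {
          # single-species genus: the species node stands in for the genus
          gen_frags <- c(gen_frags, sp_frags)
          gen_heights <- c(gen_heights, sp_heights)
        } else {
          hg <- max(jit(hG), max(sp_heights) * 1.001 + 1e-9)
          gen_frags <- c(gen_frags, sprintf("(%s)%s",
            paste(sprintf("%s:%s", sp_frags, fmt_len(hg - sp_heights)),
                  collapse = ","), gen))
          gen_heights <- c(gen_heights, hg)
        }
      }
      hf <- max(jit(hF), max(gen_heights) * 1.001 + 1e-9)
      if (length(gen_frags) == 1L) {
        # single-genus family: the genus node is the family crown
        fam_frags <- c(fam_frags, gen_frags)
        fam_heights <- c(fam_heights, gen_heights)
      } else {
        fam_frags <- c(fam_frags, sprintf("(%s)%s",
          paste(sprintf("%s:%s", gen_frags, fmt_len(hf - gen_heights)),
                collapse = ","), fam))
        fam_heights <- c(fam_heights, hf)
      }
    }
    ho <- max(jit(hO), max(fam_heights) * 1.001 + 1e-9)
    nwk <- sprintf("(%s)ROOT;",
                   paste(sprintf("%s:%s", fam_frags,
                                 fmt_len(ho - fam_heights)), collapse = ","))
    tree <- ape::read.tree(text = nwk)
    list(tree = tree, taxonomy = do.call(rbind, tax))
  })
}

# --- sequence evolution engine ----------------------------------------------

pos_classes <- function(L) rep.int(1:3, L / 3L)

# indices: encoded A=1, C=2, G=3, T=4; stops TAA=(4,1,1), TAG=(4,1,3)
find_stop_codons <- function(s) {
  c1 <- s[seq(1L, length(s), 3L)]
  c2 <- s[seq(2L, length(s), 3L)]
  c3 <- s[seq(3L, length(s), 3L)]
  which(c1 == 4L & c2 == 1L & (c3 == 1L | c3 == 3L))
}

draw_sites <- function(pi, n) sample.int(4L, n, replace = TRUE,
                                         prob = pi[BASES])

# Third base for a TA-prefixed codon: C or T (never A/G, which would form a
# stop), weighted by the conditional stationary composition so GC targets
# are preserved in expectation.
draw_third_no_stop <- function(pi, n) {
  p <- pi[c("C", "T")]
  sample(c(2L, 4L), n, replace = TRUE, prob = p / sum(p))
}

evolve_class_sites <- function(parent, P) {
  child <- integer(length(parent))
  for (b in 1:4) {
    idx <- which(parent == b)
    if (length(idx) > 0L) {
      child[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
    }
  }
  child
}

make_engine <- function(spec) {
  gc3_global <- mean(spec$gc3_targets)
  machines3 <- lapply(spec$gc3_targets, function(g)
    hky_machine(pi_pos3(g), spec$kappa))
  names(machines3) <- sprintf("F%02d", seq_len(spec$n_families))
  list(m1 = hky_machine(PI_POS1, spec$kappa),
       m2 = hky_machine(PI_POS2, spec$kappa),
       m3_global = hky_machine(pi_pos3(gc3_global), spec$kappa),
       m3_family = machines3)
}

engine_m3 <- function(engine, family) {
  if (!is.null(family) && family %in% names(engine$m3_family)) {
    engine$m3_family[[family]]
  } else {
    engine$m3_global
  }
}

# Evolve a full sequence (integer codes, frame 0) along a branch of length t,
# redrawing any codon that became a stop from its parent codon.
evolve_branch <- function(parent, t, engine, family = NULL) {
  pc <- pos_classes(length(parent))
  P1 <- engine$m1$P(t); P2 <- engine$m2$P(t)
  P3 <- engine_m3(engine, family)$P(t)
  child <- integer(length(parent))
  child[pc == 1L] <- evolve_class_sites(parent[pc == 1L], P1)
  child[pc == 2L] <- evolve_class_sites(parent[pc == 2L], P2)
  child[pc == 3L] <- evolve_class_sites(parent[pc == 3L], P3)
  # substitutions creating an in-frame stop are redrawn: the third base of a
  # TA-prefixed codon is re-sampled from its transition row restricted to
  # {C, T}, which always breaks the stop and respects the process
  stops <- find_stop_codons(child)
  if (length(stops) > 0L) {
    i3 <- (stops - 1L) * 3L + 3L
    par3 <- parent[i3]
    for (b in 1:4) {
      idx <- which(par3 == b)
      if (length(idx) > 0L) {
        p <- P3[b, c(2L, 4L)]
        child[i3[idx]] <- sample(c(2L, 4L), length(idx), replace = TRUE,
                                 prob = p / sum(p))
      }
    }
  }
  child
}

# Draw a stop-free root sequence from the stationary composition.
draw_root <- function(L, engine, family = NULL) {
  pc <- pos_classes(L)
  pi3 <- engine_m3(engine, family)$pi
  s <- integer(L)
  s[pc == 1L] <- draw_sites(engine$m1$pi, sum(pc == 1L))
  s[pc == 2L] <- draw_sites(engine$m2$pi, sum(pc == 2L))
  s[pc == 3L] <- draw_sites(pi3, sum(pc == 3L))
  stops <- find_stop_codons(s)
  s[(stops - 1L) * 3L + 3L] <- draw_third_no_stop(pi3, length(stops))
  s
}

# Redraw third positions from a family's stationary composition (used at
# family founders so each family sits at its own GC3 target).
redraw_third_positions <- function(s, engine, family) {
  pc <- pos_classes(length(s))
  pi3 <- engine_m3(engine, family)$pi
  s[pc == 3L] <- draw_sites(pi3, sum(pc == 3L))
  stops <- find_stop_codons(s)
  s[(stops - 1L) * 3L + 3L] <- draw_third_no_stop(pi3, length(stops))
  s
}

decode_seq <- function(s) paste(BASES[s], collapse = "")

#' Evolve sequences along a simulated taxonomy tree
#'
#' The root sequence is drawn codon-aware from the stationary composition
#' (stop codons rejected); each branch applies the transition-biased
#' substitution process, redrawing substitutions that would create an
#' in-frame stop under the invertebrate mitochondrial code. At each family
#' founder the third codon positions are redrawn from the family's own
#' composition, so families sit at their GC3 targets. All emitted sequences
#' are stop-free in frame 0; there are no indels.
#'
#' @param sim_tree result of \code{\link{simulate_taxonomy_tree}}
#' @param spec the \code{\link{sim_spec}} used to build the tree
#' @param seed integer seed
#' @return List with \code{dataset} (a \code{\link{barcode_dataset}}),
#'   \code{tree}, \code{taxonomy}, \code{node_seqs} (encoded sequences for
#'   every node, internals included), \code{engine} and \code{spec};
#'   consumed by \code{\link{inject_anomalies}}.
#' @export
evolve_sequences <- function(sim_tree, spec, seed) {
  tree <- sim_tree$tree
  engine <- make_engine(spec)
  ntip <- length(tree$tip.label)
  node_label <- function(node) {
    if (node <= ntip) tree$tip.label[node] else tree$node.label[node - ntip]
  }
  node_family <- function(node) {
    lab <- node_label(node)
    if (grepl("^F[0-9]{2}", lab)) substr(lab, 1L, 3L) else NULL
  }
  with_rng(seed, {
    node_seqs <- vector("list", ntip + tree$Nnode)
    root <- ntip + 1L
    node_seqs[[root]] <- draw_root(spec$sequence_length, engine)
    ord <- ape::reorder.phylo(tree, "cladewise")
    edges <- ord$edge
    elen <- ord$edge.length
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1L]; child <- edges[e, 2L]
      fam <- node_family(child)
      s <- evolve_branch(node_seqs[[parent]], elen[e], engine, fam)
      if (is.null(node_family(parent)) && !is.null(fam)) {
        # family founder (first node inside the family): impose the
        # family's third-position composition
        s <- redraw_third_positions(s, engine, fam)
      }
      node_seqs[[child]] <- s
    }
    tax <- sim_tree$taxonomy
    seqs <- vapply(match(tax$record_id, tree$tip.label),
                   function(i) decode_seq(node_seqs[[i]]), character(1))
    dataset <- barcode_dataset(data.frame(
      record_id = tax$record_id, accession = "", species = tax$species,
      genus = tax$genus, family = tax$family, sequence = seqs,
      source = "synthetic", stringsAsFactors = FALSE))
    list(dataset = dataset, tree = tree, taxonomy = tax,
         node_seqs = node_seqs, engine = engine, spec = spec)
  })
}

# Sequence (encoded) of the internal node carrying a taxon label; falls back
# to the enclosing family node, then the root, for taxa whose own node was
# elided (single-child lineages).
labelled_node_seq <- function(sim, label) {
  ntip <- length(sim$tree$tip.label)
  for (lab in c(label, substr(label, 1L, 3L), "ROOT")) {
    idx <- which(sim$tree$node.label == lab)
    if (length(idx) > 0L) return(sim$node_seqs[[ntip + idx[1L]]])
  }
  stop("no internal node labelled ", label)
}

#' Inject taxonomic anomalies with ground-truth labels
#'
#' Four anomaly classes:
#' \describe{
#'   \item{CRYPTIC}{half of a species' records are re-evolved from a point
#'     at 0.8 x d_G/2 on the species stem, creating a deep (> 2\%)
#'     intraspecific split while keeping the species monophyletic;}
#'   \item{MERGE}{one record of a congeneric species pair is replaced by a
#'     near-copy of the other species' sequence, producing non-monophyly
#'     and a sub-2\% congeneric distance in both directions;}
#'   \item{NUMT}{a record is duplicated as a pseudogene copy: third-position
#'     GC shifted down 8 points and one frameshifting deletion (position
#'     uniform over the interior third of the fragment, so both candidate
#'     frames carry out-of-frame sequence; one random base is appended to
#'     keep the alignment length);}
#'   \item{IMBALANCE}{when \code{imbalance > 1}, one species' record count
#'     is multiplied by that factor with extra records drawn from a deeper
#'     coalescence (3 x d_S/2), making it both heavily sampled and
#'     high-diversity.}
#' }
#'
#' @param sim result of \code{\link{evolve_sequences}}
#' @param spec the \code{\link{sim_spec}} (rates \code{p_cryptic},
#'   \code{p_merge}, \code{p_numt}, \code{imbalance})
#' @param seed integer seed
#' @return List with \code{dataset} (anomalies applied) and \code{truth}:
#'   \code{species} (named list species -> injected anomaly classes),
#'   \code{numt_records}, \code{expected_flags} (named list species ->
#'   flags \code{\link{flag_problem_species}} should raise) and the
#'   generating \code{tree}.
#' @export
inject_anomalies <- function(sim, spec, seed) {
  with_rng(seed, {
    ds <- as.data.frame(sim$dataset)
    engine <- sim$engine
    hG <- spec$d_G / 2; hS <- spec$d_S / 2
    truth_species <- list()
    expected_flags <- list()
    numt_records <- character(0)
    mark <- function(sp, what) truth_species[[sp]] <<-
      union(truth_species[[sp]], what)
    expect <- function(sp, flag) expected_flags[[sp]] <<-
      union(expected_flags[[sp]], flag)
    seq_of <- function(id) {
      match(strsplit(ds$sequence[ds$record_id == id], "")[[1]], BASES)
    }
    fam_of_sp <- function(sp) ds$family[match(sp, ds$species)]

    # CRYPTIC splits: a second lineage hanging off the species' own crown,
    # so the species stays monophyletic but spans two deep clusters. The
    # divergence between the two halves is ~0.8 x d_G + d_S.
    sp_tab <- unique(ds[, c("species", "genus", "family")])
    multi <- names(which(table(ds$species) >= 2L))
    for (sp in sort(intersect(sp_tab$species, multi))) {
      if (stats::runif(1) >= spec$p_cryptic) next
      fam <- fam_of_sp(sp)
      anc <- evolve_branch(labelled_node_seq(sim, sp), 0.8 * spec$d_G,
                           engine, fam)
      members <- ds$record_id[ds$species == sp]
      moved <- members[seq_len(ceiling(length(members) / 2))]
      for (id in moved) {
        ds$sequence[ds$record_id == id] <-
          decode_seq(evolve_branch(anc, hS, engine, fam))
      }
      mark(sp, "CRYPTIC"); expect(sp, "CRYPTIC")
    }

    # MERGE (haplotype sharing across a congeneric species pair)
    for (gen in sort(unique(ds$genus))) {
      sp_in_gen <- unique(ds$species[ds$genus == gen])
      sp_in_gen <- setdiff(sp_in_gen, names(truth_species))  # keep classes clean
      if (length(sp_in_gen) < 2L) next
      if (stats::runif(1) >= spec$p_merge) next
      pair <- sample(sp_in_gen, 2L)
      donor <- pair[1L]; recipient <- pair[2L]
      donor_rec <- sample(ds$record_id[ds$species == donor], 1L)
      rec_members <- ds$record_id[ds$species == recipient]
      if (length(rec_members) < 2L) next  # recipient must keep own records
      target <- sample(rec_members, 1L)
      fam <- fam_of_sp(donor)
      ds$sequence[ds$record_id == target] <-
        decode_seq(evolve_branch(seq_of(donor_rec), 0.002, engine, fam))
      mark(donor, "MERGE"); mark(recipient, "MERGE")
      expect(donor, "NON_MONOPHYLETIC"); expect(donor, "LOW_CONGENERIC")
      expect(recipient, "NON_MONOPHYLETIC")
      expect(recipient, "LOW_CONGENERIC")
      expect(recipient, "CRYPTIC")  # its records genuinely span 2 clusters
    }

    # IMBALANCE: one species heavily sampled with deeper diversity
    if (spec$imbalance > 1) {
      cand <- setdiff(sort(unique(ds$species)), names(truth_species))
      sp <- sample(cand, 1L)
      fam <- fam_of_sp(sp)
      k <- sum(ds$species == sp)
      extra <- round(k * (spec$imbalance - 1))
      h_div <- min(3 * hS, 0.9 * hG)
      anc <- evolve_branch(labelled_node_seq(sim, substr(sp, 1L, 6L)),
                           hG - h_div, engine, fam)
      if (extra > 0L) {
        row0 <- ds[ds$species == sp, ][1L, ]
        new_rows <- do.call(rbind, lapply(seq_len(extra), function(i) {
          r <- row0
          r$record_id <- sprintf("%sX%02d", sp, i)
          r$sequence <- decode_seq(evolve_branch(anc, h_div, engine, fam))
          r
        }))
        ds <- rbind(ds, new_rows)
        mark(sp, "IMBALANCE")
      }
    }

    # NUMT copies
    pc3 <- which(pos_classes(spec$sequence_length) == 3L)
    for (id in ds$record_id[stats::runif(nrow(ds)) < spec$p_numt]) {
      s <- seq_of(id)
      gc_sites <- pc3[s[pc3] %in% c(2L, 3L)]
      n_shift <- min(length(gc_sites), round(0.08 * length(pc3)))
      if (n_shift > 0L) {
        hit <- sample(gc_sites, n_shift)
        s[hit] <- sample(c(1L, 4L), n_shift, replace = TRUE)
      }
      cut <- sample(seq(floor(length(s) / 3), floor(2 * length(s) / 3)), 1L)
      s <- c(s[-cut], sample.int(4L, 1L))
      row <- ds[ds$record_id == id, ]
      row$record_id <- paste0(id, "P")
      row$sequence <- decode_seq(s)
      ds <- rbind(ds, row)
      numt_records <- c(numt_records, row$record_id)
    }

    list(dataset = barcode_dataset(ds),
         truth = list(species = truth_species,
                      expected_flags = expected_flags,
                      numt_records = numt_records,
                      tree = sim$tree))
  })
}

#' Simulate a complete barcode dataset
#'
#' Convenience wrapper: taxonomy tree, sequence evolution and anomaly
#' injection in one call, with sub-seeds derived from \code{seed} so the
#' whole dataset is a pure function of (spec, seed).
#'
#' @param spec a \code{\link{sim_spec}}
#' @param seed integer seed
#' @return List with \code{dataset}, \code{truth}, \code{tree} and
#'   \code{clean_dataset} (the pre-injection records).
#' @export
simulate_dataset <- function(spec, seed) {
  st <- simulate_taxonomy_tree(spec, seed)
  evo <- evolve_sequences(st, spec, seed + 1L)
  inj <- inject_anomalies(evo, spec, seed + 2L)
  list(dataset = inj$dataset, truth = inj$truth, tree = st$tree,
       clean_dataset = evo$dataset)
}
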