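#' Simulation specification
#'
#' The stated world for the desk-scale benchmark: a hierarchical bacterial
#' reference (phyla / genera / species), a pool of organelle amplicon variants
#' diverged from a hidden common ancestor (the variants absent from the base
#' reference are the "cryptic" organelles), and a two-group study whose groups
#' share the same true microbiome but differ in organelle load.
#'
#' Divergences are per-site substitution probabilities. Defaults: 3 phyla x 4
#' genera x 3 species of 250-nt amplicons; organelle pool of 12 variants at
#' divergence 0.20 (within the reported range of intra-individual 12S rRNA
#' divergence, which reaches ~23% in lobster); a quarter of the pool present in
#' the base reference; 2 groups x 10 samples x 500 reads; organelle loads 5%
#' and 30% of reads per group; sequencing error 0.001/base.
#'
#' @param n_phyla,genera_per_phylum,species_per_genus reference shape.
#' @param seq_len amplicon length (nt).
#' @param within_genus_divergence species-to-genus-founder divergence.
#' @param between_phylum_divergence genus-founder-to-phylum-root divergence
#'   (phylum roots themselves are independent random sequences).
#' @param organelle_pool_size number of organelle variants.
#' @param organelle_divergence per-site divergence of each variant from the
#'   hidden organelle ancestor.
#' @param base_db_organelle_fraction fraction of the pool present in the base
#'   reference (the rest is cryptic).
#' @param n_samples_per_group,reads_per_sample study shape.
#' @param organelle_load_by_group named numeric: per-group fraction of reads
#'   of organelle origin.
#' @param sequencing_error_rate per-base substitution probability applied to
#'   every simulated read.
#' @param dirichlet_concentration overdispersion of per-sample community
#'   proportions around the shared base composition.
#' @param cryptic_read_weight how strongly organelle reads favour cryptic
#'   variants over base-subset variants (per-variant sampling weight ratio).
#' @param seed default seed threaded through the generators.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_phyla = 3L, genera_per_phylum = 4L,
                     species_per_genus = 3L, seq_len = 250L,
                     within_genus_divergence = 0.02,
                     between_phylum_divergence = 0.25,
                     organelle_pool_size = 12L, organelle_divergence = 0.20,
                     base_db_organelle_fraction = 0.25,
                     n_samples_per_group = 10L, reads_per_sample = 500L,
                     organelle_load_by_group = c(A = 0.05, B = 0.30),
                     sequencing_error_rate = 0.001,
                     dirichlet_concentration = 50,
                     cryptic_read_weight = 4,
                     seed = 0L) {
  stopifnot(within_genus_divergence < between_phylum_divergence,
            organelle_divergence >= 0, organelle_divergence <= 1,
            base_db_organelle_fraction >= 0, base_db_organelle_fraction <= 1,
            all(organelle_load_by_group >= 0),
            all(organelle_load_by_group <= 1),
            reads_per_sample >= 1L, organelle_pool_size >= 1L,
            sequencing_error_rate >= 0, sequencing_error_rate <= 1)
  if (is.null(names(organelle_load_by_group)))
    names(organelle_load_by_group) <-
      LETTERS[seq_along(organelle_load_by_group)]
  structure(list(
    n_phyla = as.integer(n_phyla),
    genera_per_phylum = as.integer(genera_per_phylum),
    species_per_genus = as.integer(species_per_genus),
    seq_len = as.integer(seq_len),
    within_genus_divergence = within_genus_divergence,
    between_phylum_divergence = between_phylum_divergence,
    organelle_pool_size = as.integer(organelle_pool_size),
    organelle_divergence = organelle_divergence,
    base_db_organelle_fraction = base_db_organelle_fraction,
    n_samples_per_group = as.integer(n_samples_per_group),
    reads_per_sample = as.integer(reads_per_sample),
    organelle_load_by_group = organelle_load_by_group,
    sequencing_error_rate = sequencing_error_rate,
    dirichlet_concentration = dirichlet_concentration,
    cryptic_read_weight = cryptic_read_weight,
    seed = as.integer(seed)), class = "sim_spec")
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

# Substitute each position independently with probability `rate`, to a
# uniformly chosen different base.
mutate_sequence <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit) > 0) {
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1))
  }
  paste(chars, collapse = "")
}

#' Generate a hierarchical bacterial reference and matching tree
#'
#' Phylum root sequences are independent uniform random DNA; genus founders
#' derive from their phylum root at `between_phylum_divergence`, species from
#' their genus founder at `within_genus_divergence` (seeded point
#' substitutions). Lineages are synthesised as Phylum_i / Genus_ij /
#' Species_ijk with filled intermediate ranks, in SILVA dialect. The returned
#' tree has the same topology with branch lengths proportional to the
#' substitution rates; tips are the reference ids.
#'
#' @param spec a [sim_spec()].
#' @param seed overrides `spec$seed`.
#' @return list: `db` (a `reference_db`), `tree` (`ape::phylo`).
#' @export
generate_reference <- function(spec = sim_spec(), seed = spec$seed) {
  with_seed(seed, {
    seqs <- character(0)
    tax <- character(0)
    genus_clades <- list()
    phylum_clades <- character(spec$n_phyla)
    for (p in seq_len(spec$n_phyla)) {
      root <- random_dna(spec$seq_len)
      genus_newick <- character(spec$genera_per_phylum)
      for (g in seq_len(spec$genera_per_phylum)) {
        founder <- mutate_sequence(root, spec$between_phylum_divergence)
        tips <- character(spec$species_per_genus)
        for (s in seq_len(spec$species_per_genus)) {
          id <- sprintf("sp_p%d_g%d_s%d", p, g, s)
          seqs[[id]] <- mutate_sequence(founder, spec$within_genus_divergence)
          tax[[id]] <- sprintf(
            "d__Bacteria; p__Phylum_%d; c__Class_%d; o__Order_%d_%d; f__Family_%d_%d; g__Genus_%d_%d; s__Species_%d_%d_%d",
            p, p, p, g, p, g, p, g, p, g, s)
          tips[s] <- sprintf("%s:%g", id, spec$within_genus_divergence)
        }
        genus_newick[g] <- sprintf("(%s):%g", paste(tips, collapse = ","),
                                   spec$between_phylum_divergence)
      }
      phylum_clades[p] <- sprintf("(%s):0.375",
                                  paste(genus_newick, collapse = ","))
    }
    tree <- ape::read.tree(
      text = paste0("(", paste(phylum_clades, collapse = ","), ");"))
    list(db = reference_db(seqs, tax, "silva"), tree = tree)
  })
}

#' Generate an organelle amplicon pool with cryptic variants
#'
#' A hidden ancestral organelle core sequence is generated far from all
#' bacterial references (rejection sampling against a 0.75 global-query
#' identity ceiling; error after 100 attempts). Each pool member is an
#' independent variant of that ancestor at divergence `organelle_divergence`,
#' flanked by intact (conserved) primer sites and short flanks so that
#' [extend_reference()] can amplicon-extract it. The first
#' `ceiling(base_db_organelle_fraction * organelle_pool_size)` ids form the
#' base subset (present in the base reference); the rest are the cryptic
#' variants. Because the variants diverge independently, cryptic variants sit
#' at roughly 1 - 2d(1-d) - (2/3)d^2 identity to any base-subset member —
#' below the classifier's acceptance threshold at the default d = 0.20, which
#' is exactly the annotation gap the toolkit audits.
#'
#' @param spec a [sim_spec()].
#' @param reference optional `reference_db` the ancestor must stay distant
#'   from; defaults to [generate_reference()] under the same seed.
#' @param primers primer pair used for the embedded sites.
#' @param seed overrides `spec$seed`.
#' @return list: `pool` (data frame `id`, `seq` of full records with primer
#'   sites), `base_subset` (ids), `cryptic` (ids), `ancestor` (hidden ancestral
#'   core), `cores` (named character: inter-primer core per variant).
#' @export
generate_organelle_pool <- function(spec = sim_spec(), reference = NULL,
                                    primers = primer_pair(), seed = spec$seed) {
  if (is.null(reference)) reference <- generate_reference(spec, seed = seed)$db
  with_seed(seed + 1L, {
    ancestor <- NULL
    for (attempt in seq_len(100L)) {
      cand <- random_dna(spec$seq_len)
      ids <- vapply(unname(reference$seqs), function(r)
        align_batch(cand, r, mode = "query_global")$identity[1], numeric(1))
      if (all(ids < 0.75)) { ancestor <- cand; break }
    }
    if (is.null(ancestor))
      stop("could not construct an organelle ancestor below the 0.75 ",
           "identity ceiling in 100 attempts")
    # concrete (conserved) primer sites shared by all pool members
    fwd_site <- resolve_degenerate(primers$forward)
    rev_site <- revcomp(resolve_degenerate(primers$reverse))
    flank5 <- random_dna(10L)
    flank3 <- random_dna(10L)
    n <- spec$organelle_pool_size
    ids <- sprintf("mito_%02d", seq_len(n))
    cores <- setNames(vapply(seq_len(n), function(i)
      mutate_sequence(ancestor, spec$organelle_divergence), character(1)), ids)
    pool <- data.frame(
      id = ids,
      seq = paste0(flank5, fwd_site, unname(cores), rev_site, flank3),
      stringsAsFactors = FALSE)
    n_base <- min(n, ceiling(spec$base_db_organelle_fraction * n))
    base_subset <- ids[seq_len(n_base)]
    list(pool = pool, base_subset = base_subset,
         cryptic = setdiff(ids, base_subset),
         ancestor = ancestor, cores = cores)
  })
}

# One concrete instantiation of a degenerate primer (first base of each set;
# deterministic, so all simulated organelles share identical primer sites).
resolve_degenerate <- function(primer) {
  chars <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(c) IUPAC_SETS[[c]][1], character(1)),
        collapse = "")
}

#' Base and extended references for a simulated study
#'
#' Builds the base reference (bacteria + the base-subset organelle variants)
#' and the extended reference (bacteria + the full pool) via
#' [extend_reference()] with the same primers used to embed the sites.
#'
#' @param reference bacterial `reference_db`.
#' @param pool,base_subset from [generate_organelle_pool()].
#' @param primers primer pair.
#' @return list: `base`, `extended` (both `reference_db`).
#' @export
build_study_references <- function(reference, pool, base_subset,
                                   primers = primer_pair()) {
  base <- extend_reference(reference, pool[pool$id %in% base_subset, ],
                           kind = "mitochondria", primers = primers)
  extended <- extend_reference(reference, pool, kind = "mitochondria",
                               primers = primers)
  list(base = base, extended = extended)
}

#' Conceptual worked example: organelle load distorting relative abundance
#'
#' One community per entry of `organelle_counts`: `n_microbes` distinct
#' microbial features (one read each; the first is the focal microbe) plus `m`
#' organelle reads split across two variants ("light" gets the floor half,
#' "dark" the rest). The apparent relative abundance of the focal microbe is
#' reported under three scenarios: no filtering, partial filtering (only the
#' dark variant recognised and removed), and perfect filtering (all organelle
#' reads removed) — under perfect filtering the focal abundance is 1/n_microbes
#' in every community regardless of organelle load.
#'
#' @param organelle_counts integer vector, organelle reads per community
#'   (default `c(6, 3, 0)`: many, some, none).
#' @param n_microbes microbes per community (default 3, so the focal microbe's
#'   true abundance is 1/3).
#' @return list: `table` (feature table, communities as samples), `truth`
#'   (feature origins), `focal_abundance` (data frame: community,
#'   no_filtering, partial_filtering, perfect_filtering).
#' @export
simulate_bias_communities <- function(organelle_counts = c(6L, 3L, 0L),
                                      n_microbes = 3L) {
  stopifnot(n_microbes >= 1L)
  if (any(organelle_counts < 0)) stop("negative organelle count")
  k <- length(organelle_counts)
  features <- c(paste0("microbe_", seq_len(n_microbes)),
                "org_light", "org_dark")
  tab <- matrix(0L, nrow = length(features), ncol = k,
                dimnames = list(features,
                                paste0("community_", seq_len(k))))
  tab[seq_len(n_microbes), ] <- 1L
  light <- floor(organelle_counts / 2)
  dark <- organelle_counts - light
  tab["org_light", ] <- as.integer(light)
  tab["org_dark", ] <- as.integer(dark)
  truth <- data.frame(
    feature_id = features,
    origin = c(rep("bacteria", n_microbes), "organelle", "organelle"),
    stringsAsFactors = FALSE)
  focal <- data.frame(
    community = colnames(tab),
    organelle_reads = as.integer(organelle_counts),
    no_filtering = 1 / (n_microbes + organelle_counts),
    partial_filtering = 1 / (n_microbes + light),
    perfect_filtering = rep(1 / n_microbes, k))
  list(table = validate_feature_table(tab), truth = truth,
       focal_abundance = focal)
}

#' Simulate a two-group amplicon study with group-varying organelle load
#'
#' Per sample, bacterial reads are drawn from a Dirichlet-multinomial over all
#' reference species (the base composition is shared across groups, so the
#' true microbiomes are exchangeable), and organelle reads are added at the
#' sample's group load, drawn preferentially from cryptic variants
#' (`cryptic_read_weight` : 1 per variant). Per-base sequencing errors are
#' applied to every read; identical reads are then collapsed to features.
#'
#' @param spec a [sim_spec()].
#' @param reference bacterial `reference_db` (defaults regenerate from spec).
#' @param pool output of [generate_organelle_pool()] (defaults regenerate).
#' @param seed overrides `spec$seed`.
#' @return list: `queries` (data frame `id`, `seq` of unique feature
#'   sequences), `table` (feature table), `metadata` (`sample_id`, `group`),
#'   `truth` (per-feature `feature_id`, `origin` (`bacteria`/`organelle`),
#'   `source_id`, `cryptic`; plus per-sample `sample_truth` with the realised
#'   organelle load).
#' @export
simulate_study <- function(spec = sim_spec(), reference = NULL, pool = NULL,
                           seed = spec$seed) {
  if (is.null(reference)) reference <- generate_reference(spec, seed = seed)$db
  if (is.null(pool)) pool <- generate_organelle_pool(spec, reference,
                                                     seed = seed)
  loads <- spec$organelle_load_by_group
  if (any(loads > 1)) stop("organelle load > 1")
  species_ids <- names(reference$seqs)
  var_ids <- names(pool$cores)
  w <- ifelse(var_ids %in% pool$cryptic, spec$cryptic_read_weight, 1)
  with_seed(seed + 2L, {
    base_comp <- as.numeric(rgamma(length(species_ids), shape = 1))
    base_comp <- base_comp / sum(base_comp)
    groups <- names(loads)
    sample_ids <- character(0)
    sample_groups <- character(0)
    read_seqs <- list()
    read_origin <- list()
    n_org_real <- integer(0)
    for (g in groups) {
      for (i in seq_len(spec$n_samples_per_group)) {
        sid <- sprintf("%s_%02d", g, i)
        n_org <- rbinom(1L, spec$reads_per_sample, loads[[g]])
        n_bact <- spec$reads_per_sample - n_org
        # per-sample composition: Dirichlet around the shared base
        alpha <- spec$dirichlet_concentration * base_comp
        p <- rgamma(length(alpha), shape = alpha)
        p <- p / sum(p)
        bact_counts <- as.integer(rmultinom(1L, n_bact, p))
        org_counts <- if (n_org > 0)
          as.integer(rmultinom(1L, n_org, w / sum(w)))
        else integer(length(var_ids))
        src <- c(rep(species_ids, bact_counts), rep(var_ids, org_counts))
        tmpl <- c(rep(unname(reference$seqs), bact_counts),
                  rep(unname(pool$cores), org_counts))
        reads <- apply_sequencing_errors(tmpl, spec$sequencing_error_rate)
        sample_ids <- c(sample_ids, sid)
        sample_groups <- c(sample_groups, g)
        read_seqs[[sid]] <- reads
        read_origin[[sid]] <- src
        n_org_real <- c(n_org_real, n_org)
      }
    }
    # collapse identical read sequences into features
    all_seqs <- unlist(read_seqs, use.names = FALSE)
    all_src <- unlist(read_origin, use.names = FALSE)
    uniq <- unique(all_seqs)
    # deterministic feature order: total count descending, then sequence
    totals <- table(factor(all_seqs, levels = uniq))
    ord <- order(-as.integer(totals), uniq, method = "radix")
    uniq <- uniq[ord]
    fid <- sprintf("asv_%05d", seq_along(uniq))
    names(fid) <- uniq
    tab <- matrix(0L, nrow = length(uniq), ncol = length(sample_ids),
                  dimnames = list(fid, sample_ids))
    for (sid in sample_ids) {
      cnt <- table(factor(read_seqs[[sid]], levels = uniq))
      tab[, sid] <- as.integer(cnt)
    }
    # per-feature truth: the source of the first read carrying the sequence
    first <- match(uniq, all_seqs)
    src_id <- all_src[first]
    truth <- data.frame(
      feature_id = unname(fid),
      origin = ifelse(src_id %in% var_ids, "organelle", "bacteria"),
      source_id = src_id,
      cryptic = src_id %in% pool$cryptic,
      stringsAsFactors = FALSE)
    list(queries = data.frame(id = unname(fid), seq = uniq,
                              stringsAsFactors = FALSE),
         table = validate_feature_table(tab),
         metadata = data.frame(sample_id = sample_ids, group = sample_groups,
                               stringsAsFactors = FALSE),
         truth = truth,
         sample_truth = data.frame(sample_id = sample_ids,
                                   group = sample_groups,
                                   organelle_reads = n_org_real,
                                   load = n_org_real / spec$reads_per_sample,
                                   stringsAsFactors = FALSE))
  })
}

# vectorised per-base substitution errors over a character vector of reads
apply_sequencing_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  lens <- nchar(reads)
  n_err <- rbinom(length(reads), lens, rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(lens[i], n_err[i])
    chars[pos] <- vapply(chars[pos], function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1))
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Shuffle sequences (composition-preserving artifacts)
#'
#' Each sequence's characters are permuted uniformly at random (seeded); ids
#' get a `.shuf` suffix. Used as the negative-control artifact set: shuffled
#' sequences keep their nucleotide composition but lose all positional signal.
#'
#' @param records data frame (`id`, `seq`) or named character vector.
#' @param seed RNG seed.
#' @return data frame (`id`, `seq`).
#' @export
shuffle_sequences <- function(records, seed = 0L) {
  if (is.data.frame(records)) records <- setNames(records$seq, records$id)
  if (length(records) == 0L) stop("no records to shuffle")
  with_seed(seed, {
    shuf <- vapply(unname(records), function(s) {
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      paste(chars[sample.int(length(chars))], collapse = "")
    }, character(1))
    data.frame(id = paste0(names(records), ".shuf"), seq = unname(shuf),
               stringsAsFactors = FALSE)
  })
}

#' Organelle-free mock community fixture
#'
#' The same study generator with every group's organelle load forced to zero:
#' samples are composed only of bacterial reads and the truth table records no
#' organelle-origin features. Any mitochondrial annotation on this fixture is
#' a false positive.
#'
#' @param spec a [sim_spec()].
#' @param reference,pool,seed as in [simulate_study()].
#' @return as [simulate_study()].
#' @export
generate_mock_fixture <- function(spec = sim_spec(), reference = NULL,
                                  pool = NULL, seed = spec$seed) {
  spec$organelle_load_by_group[] <- 0
  simulate_study(spec, reference = reference, pool = pool, seed = seed)
}
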