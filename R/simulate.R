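#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic dataset generator:
#' a ranked taxonomy over a species tree, per-domain families evolving
#' vertically, horizontal transfer of a domain cassette from a prokaryote
#' donor into taxonomically disjoint eukaryote recipients, fusion of the
#' transferred cassette into one multidomain protein, plus length outliers
#' and split fragments for the curation stage to clean up.
#'
#' The defaults describe the study condition the package's end-to-end
#' recovery experiments use: 40 species in 6 groups (three prokaryotic
#' donor-side groups, three eukaryotic), a three-domain
#' CrtI/CrtB/CrtYc-d cassette transferred from one Actinobacteria tip into
#' one recipient in each eukaryote group with post-transfer mutation scale
#' 0.1, substitution rate 0.2 per site per unit branch length, and a
#' vertically inherited Rpe65 family present in every species.
#'
#' @param group_spec Tibble with columns `group`, `cell_domain`, `n`
#'   (species counts per group; groups are monophyletic in the species
#'   tree).
#' @param branch_length_mean Mean of the i.i.d. exponential branch lengths.
#' @param subst_rate Per-site substitution rate per unit branch length.
#' @param domain_lengths Named integer vector of domain residue counts
#'   (each at least 30).
#' @param hgt_events List of events; each a list with `donor_species`,
#'   `recipients` (species ids), `cassette` (ordered domain names) and
#'   `post_transfer_scale`.
#' @param fusion_linker Residue string inserted between fused domains.
#' @param outlier_fraction Fraction of records turned into length outliers.
#' @param fragment_fraction Fraction of records split into two fragments
#'   sharing a `parent_id`.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration including this seed.
#' @param disjoint_recipients Require recipients to come from groups
#'   distinct from the donor's and from each other's.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(group_spec = default_group_spec(),
                       branch_length_mean = 0.3,
                       subst_rate = 0.2,
                       domain_lengths = c(
                         CrtI = 500L, CrtB = 300L, `CrtYc/d` = 120L,
                         Rpe65 = 530L
                       ),
                       hgt_events = default_hgt_events(),
                       fusion_linker = "GS",
                       outlier_fraction = 0.1,
                       fragment_fraction = 0.05,
                       seed = 1L,
                       disjoint_recipients = TRUE) {
  cfg <- list(
    group_spec = as_tibble(group_spec),
    n_species = sum(group_spec$n),
    branch_length_mean = branch_length_mean,
    subst_rate = subst_rate,
    domain_lengths = domain_lengths,
    hgt_events = hgt_events,
    fusion_linker = fusion_linker,
    outlier_fraction = outlier_fraction,
    fragment_fraction = fragment_fraction,
    seed = as.integer(seed),
    disjoint_recipients = disjoint_recipients
  )
  if (!all(c("group", "cell_domain", "n") %in% names(cfg$group_spec))) {
    abort("group_spec needs columns group, cell_domain, n")
  }
  if (cfg$n_species < 4) abort("need at least 4 species")
  if (branch_length_mean <= 0) abort("branch_length_mean must be positive")
  if (subst_rate < 0) abort("subst_rate must be non-negative")
  if (any(domain_lengths < 30)) abort("domain lengths must be at least 30 residues")
  if (outlier_fraction < 0 || outlier_fraction >= 1 ||
    fragment_fraction < 0 || fragment_fraction >= 1) {
    abort("outlier_fraction and fragment_fraction must lie in [0, 1)")
  }
  species_by_group <- species_names(cfg$group_spec)
  for (ev in cfg$hgt_events) {
    needed <- c("donor_species", "recipients", "cassette", "post_transfer_scale")
    if (!all(needed %in% names(ev))) {
      abort(paste0("each hgt event needs: ", paste(needed, collapse = ", ")))
    }
    all_sp <- unlist(species_by_group)
    if (!ev$donor_species %in% all_sp) abort("unknown donor_species")
    if (!all(ev$recipients %in% all_sp)) abort("unknown recipient species")
    if (!all(ev$cassette %in% names(domain_lengths))) {
      abort("cassette domains must appear in domain_lengths")
    }
    if (ev$post_transfer_scale < 0) abort("post_transfer_scale must be >= 0")
    if (cfg$disjoint_recipients) {
      grp_of <- rep(names(species_by_group), lengths(species_by_group))
      names(grp_of) <- all_sp
      rg <- grp_of[ev$recipients]
      if (anyDuplicated(rg) || grp_of[ev$donor_species] %in% rg) {
        abort("recipients must come from groups distinct from the donor's and from each other's")
      }
      cd <- cfg$group_spec$cell_domain[match(rg, cfg$group_spec$group)]
      if (!all(cd == "eukaryote")) abort("recipients must be eukaryotic")
    }
  }
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_group_spec <- function() {
  tibble(
    group = c(
      "Actinobacteria", "Bacteroidetes", "Halobacteria",
      "Stramenopila", "Alveolata", "Obazoa"
    ),
    cell_domain = rep(c("prokaryote", "eukaryote"), each = 3),
    n = c(7L, 7L, 6L, 7L, 7L, 6L)
  )
}

#' @rdname sim_config
#' @export
default_hgt_events <- function() {
  list(list(
    donor_species = "Actinobacteria_sp01",
    recipients = c("Stramenopila_sp01", "Alveolata_sp01", "Obazoa_sp01"),
    cassette = c("CrtI", "CrtB", "CrtYc/d"),
    post_transfer_scale = 0.1
  ))
}

species_names <- function(group_spec) {
  out <- lapply(seq_len(nrow(group_spec)), function(i) {
    sprintf("%s_sp%02d", group_spec$group[i], seq_len(group_spec$n[i]))
  })
  names(out) <- group_spec$group
  out
}

# Yule tip-splitting topology over `labels`; returns a newick fragment
# (no outer branch length), drawing exponential branch lengths as it goes.
yule_fragment <- function(labels, bl_mean) {
  n <- length(labels)
  if (n == 1) {
    return(labels)
  }
  kids <- vector("list", 2 * n)
  tips <- 1L
  next_id <- 2L
  while (length(tips) < n) {
    pick <- tips[sample.int(length(tips), 1)]
    kids[[pick]] <- c(next_id, next_id + 1L)
    tips <- c(setdiff(tips, pick), next_id, next_id + 1L)
    next_id <- next_id + 2L
  }
  tip_label <- setNames(labels, tips)
  build <- function(v) {
    ch <- kids[[v]]
    if (is.null(ch)) {
      return(tip_label[[as.character(v)]])
    }
    left <- paste0(build(ch[1]), ":", fmt_len(rexp(1, 1 / bl_mean)))
    right <- paste0(build(ch[2]), ":", fmt_len(rexp(1, 1 / bl_mean)))
    paste0("(", left, ",", right, ")")
  }
  build(1L)
}

#' Simulate a species tree with a ranked taxonomy
#'
#' Grows a random bifurcating tree by repeatedly splitting a uniformly
#' chosen tip (a Yule process), with i.i.d. exponential branch lengths.
#' Groups are kept monophyletic by growing a Yule backbone over the groups
#' and a Yule subtree within each group. The taxonomy carries the ranks
#' `cell_domain`, `group`, `species`.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed; omit when calling from [build_dataset()],
#'   which seeds the single RNG stream once.
#' @return A list: `tree` (rooted `phylo`), `taxonomy` (tibble keyed by
#'   species id).
#' @export
simulate_species_tree <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  sp <- species_names(config$group_spec)
  frags <- vapply(
    sp, yule_fragment, character(1),
    bl_mean = config$branch_length_mean
  )
  txt <- if (length(frags) == 1) {
    paste0(frags[[1]], ";")
  } else {
    placeholders <- sprintf("GROUPSLOT%03d", seq_along(frags))
    backbone <- paste0(yule_fragment(placeholders, config$branch_length_mean), ";")
    for (i in seq_along(frags)) {
      backbone <- sub(placeholders[i], frags[[i]], backbone, fixed = TRUE)
    }
    backbone
  }
  tree <- read_newick(txt)
  taxonomy <- tibble(
    seq_id = unlist(sp, use.names = FALSE),
    cell_domain = rep(config$group_spec$cell_domain, config$group_spec$n),
    group = rep(config$group_spec$group, config$group_spec$n),
    species = unlist(sp, use.names = FALSE)
  )
  list(tree = tree, taxonomy = taxonomy)
}

# mutate each site independently with probability p; a mutating site is
# replaced by a uniformly chosen *different* residue
mutate_chars <- function(chars, p) {
  if (p <= 0) {
    return(chars)
  }
  hit <- which(runif(length(chars)) < p)
  if (length(hit) > 0) {
    cur_idx <- match(chars[hit], AA20)
    pick <- sample.int(19L, length(hit), replace = TRUE)
    new_idx <- ifelse(pick >= cur_idx, pick + 1L, pick)
    chars[hit] <- AA20[new_idx]
  }
  chars
}

#' Evolve a domain family down a tree
#'
#' Simple substitution-only evolution: along each branch of length `t`,
#' every site mutates independently with probability `1 - exp(-rate * t)`;
#' a mutating site is replaced by a uniformly chosen different residue.
#' There are no indels, so the site-wise identity is the true alignment.
#'
#' @param tree Rooted `phylo` species tree.
#' @param root_sequence Gap-free residue string at the root.
#' @param subst_rate Per-site rate per unit branch length (>= 0).
#' @param seed Optional seed.
#' @return Named character vector of tip sequences.
#' @export
evolve_domain <- function(tree, root_sequence, subst_rate, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (grepl("-", root_sequence, fixed = TRUE)) abort("root_sequence must be gap-free")
  if (subst_rate < 0) abort("subst_rate must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  seq_at <- vector("list", nn)
  seq_at[[ntip + 1]] <- strsplit(root_sequence, "")[[1]]
  ordered <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ordered$edge))) {
    p <- ordered$edge[k, 1]
    c <- ordered$edge[k, 2]
    t <- ordered$edge.length[k]
    seq_at[[c]] <- mutate_chars(seq_at[[p]], 1 - exp(-subst_rate * t))
  }
  out <- vapply(seq_len(ntip), function(t) paste(seq_at[[t]], collapse = ""), character(1))
  setNames(out, tree$tip.label)
}

#' Transfer a domain cassette horizontally
#'
#' Copies the donor tip's cassette domain sequences into each recipient.
#' The copies pass through one shared mutation round at the effective rate
#' `subst_rate * post_transfer_scale` (the unsampled proximate donor
#' lineage common to the repeated transfers) and then one independent round
#' per recipient at the same rate. With `post_transfer_scale = 0` every
#' recipient carries an exact copy of the donor sequence.
#'
#' @param tip_sequences Named list: domain -> named character vector of
#'   carrier tip sequences.
#' @param donor_tip Donor species id (must carry every cassette domain).
#' @param recipients Recipient species ids (must not already carry them).
#' @param cassette Ordered domain names to transfer.
#' @param subst_rate Base substitution rate.
#' @param post_transfer_scale Non-negative multiplier on `subst_rate`.
#' @param seed Optional seed.
#' @return A list: `tip_sequences` (updated), `recipient_ids`.
#' @export
apply_hgt <- function(tip_sequences, donor_tip, recipients, cassette,
                      subst_rate, post_transfer_scale, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (post_transfer_scale < 0) abort("post_transfer_scale must be >= 0")
  if (length(recipients) == 0) {
    return(list(tip_sequences = tip_sequences, recipient_ids = character()))
  }
  p_eff <- 1 - exp(-subst_rate * post_transfer_scale)
  for (dom in cassette) {
    carriers <- tip_sequences[[dom]]
    if (is.null(carriers) || !donor_tip %in% names(carriers)) {
      abort(paste0("donor '", donor_tip, "' does not carry cassette domain '", dom, "'"))
    }
    already <- intersect(recipients, names(carriers))
    if (length(already) > 0) {
      abort(paste0(
        "recipient(s) already carry domain '", dom, "': ",
        paste(already, collapse = ", ")
      ))
    }
    donor_chars <- strsplit(carriers[[donor_tip]], "")[[1]]
    shared <- mutate_chars(donor_chars, p_eff)
    for (r in recipients) {
      carriers[[r]] <- paste(mutate_chars(shared, p_eff), collapse = "")
    }
    tip_sequences[[dom]] <- carriers
  }
  list(tip_sequences = tip_sequences, recipient_ids = recipients)
}

divergence_from <- function(seq, ref) {
  a <- strsplit(seq, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  mean(a != b)
}

#' Fuse domain sequences into one multidomain protein
#'
#' Concatenates domains N- to C-terminal with a linker between consecutive
#' domains and emits exact envelope coordinates as ground-truth domain
#' hits. The synthetic bit score of each domain is
#' `length * (1 - divergence from the domain's root sequence)` — monotone
#' in completeness and conservation, which is all downstream dereplication
#' needs from it.
#'
#' @param domain_sequences Named character vector: domain -> residues.
#' @param order Ordered domain names to fuse (at least one).
#' @param linker Residue string placed between consecutive domains.
#' @param seq_id Id of the fused protein.
#' @param root_sequences Optional named character vector of root sequences
#'   used for the divergence term (absent domains count as divergence 0).
#' @return A list: `record` (one-row sequence tibble), `hits` (tibble of
#'   ground-truth domain hits).
#' @examples
#' fuse_domains(
#'   c(A = strrep("M", 40), B = strrep("K", 30)),
#'   order = c("A", "B"), linker = "GS", seq_id = "p1"
#' )$hits
#' @export
fuse_domains <- function(domain_sequences, order, linker = "GS",
                         seq_id = "fused", root_sequences = NULL) {
  if (length(order) == 0) abort("fusion order must list at least one domain")
  if (!all(order %in% names(domain_sequences))) {
    abort("every domain in `order` must be present in domain_sequences")
  }
  residues <- ""
  hits <- tibble(
    seq_id = character(), domain = character(),
    env_start = integer(), env_end = integer(),
    bit_score = numeric(), e_value = numeric()
  )
  pos <- 0L
  for (k in seq_along(order)) {
    dom <- order[k]
    s <- domain_sequences[[dom]]
    if (k > 1) {
      residues <- paste0(residues, linker)
      pos <- pos + nchar(linker)
    }
    start <- pos + 1L
    end <- pos + nchar(s)
    div <- if (!is.null(root_sequences) && dom %in% names(root_sequences)) {
      divergence_from(s, root_sequences[[dom]])
    } else {
      0
    }
    hits <- bind_rows(hits, tibble(
      seq_id = seq_id, domain = dom,
      env_start = start, env_end = end,
      bit_score = nchar(s) * (1 - div), e_value = 0
    ))
    residues <- paste0(residues, s)
    pos <- end
  }
  list(
    record = tibble(id = seq_id, description = "", residues = residues),
    hits = hits
  )
}

sanitise_domain <- function(x) gsub("[^A-Za-z0-9]", "", x)

#' Build a complete synthetic dataset with ground truth
#'
#' Runs the full generator: species tree and taxonomy, vertical evolution
#' of every domain family, horizontal transfer of the configured cassettes,
#' fusion of transferred cassettes into multidomain recipient proteins,
#' per-protein domain hits with synthetic bit scores, and injection of
#' length outliers and split fragments for the curation stage. Cassette
#' domains are carried vertically by prokaryotes only; all other domains by
#' every species. The output is a deterministic function of the
#' configuration (including its seed).
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `proteins.fasta`,
#'   `full_proteins.fasta`, `taxonomy.tsv`, `hits.tsv`, `scores.tsv` and a
#'   `truth/` subdirectory of plain-text ground truth.
#' @return A list: `proteins`, `full_proteins` (pre-outlier,
#'   pre-fragmentation records), `taxonomy` (protein-level), `hits`,
#'   `scores`, and `truth` (species tree, species taxonomy, root and tip
#'   sequences per domain, recipient ids, donor clade, architectures,
#'   outlier and fragment ids).
#' @export
build_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  st <- simulate_species_tree(config)
  species_tax <- st$taxonomy
  domains <- names(config$domain_lengths)
  cassette_domains <- unique(unlist(lapply(config$hgt_events, `[[`, "cassette")))
  prok <- species_tax$seq_id[species_tax$cell_domain == "prokaryote"]

  root_seqs <- vapply(domains, function(dom) {
    paste(sample(AA20, config$domain_lengths[[dom]], replace = TRUE), collapse = "")
  }, character(1))

  tipseqs <- lapply(domains, function(dom) {
    evolve_domain(st$tree, root_seqs[[dom]], config$subst_rate)
  })
  names(tipseqs) <- domains
  # cassette domains are vertically present in prokaryotes only
  for (dom in cassette_domains) tipseqs[[dom]] <- tipseqs[[dom]][prok]

  recipients_of <- list() # species -> event index
  for (i in seq_along(config$hgt_events)) {
    ev <- config$hgt_events[[i]]
    res <- apply_hgt(
      tipseqs, ev$donor_species, ev$recipients, ev$cassette,
      config$subst_rate, ev$post_transfer_scale
    )
    tipseqs <- res$tip_sequences
    for (r in ev$recipients) recipients_of[[r]] <- i
  }

  proteins <- tibble(id = character(), description = character(), residues = character())
  hits <- tibble(
    seq_id = character(), domain = character(),
    env_start = integer(), env_end = integer(),
    bit_score = numeric(), e_value = numeric()
  )
  architectures <- tibble(seq_id = character(), architecture = character())
  owner <- character() # species owning each protein id

  add_protein <- function(species, order, pid) {
    doms <- setNames(
      vapply(order, function(d) tipseqs[[d]][[species]], character(1)),
      order
    )
    fz <- fuse_domains(doms, order, config$fusion_linker, pid, root_seqs)
    proteins <<- bind_rows(proteins, fz$record)
    hits <<- bind_rows(hits, fz$hits)
    architectures <<- bind_rows(architectures, tibble(
      seq_id = pid, architecture = paste(order, collapse = "+")
    ))
    owner[pid] <<- species
  }

  for (species in species_tax$seq_id) {
    if (species %in% names(recipients_of)) {
      ev <- config$hgt_events[[recipients_of[[species]]]]
      add_protein(species, ev$cassette, paste0(species, "_fused"))
    }
    for (dom in domains) {
      if (dom %in% cassette_domains && species %in% names(recipients_of)) next
      if (!species %in% names(tipseqs[[dom]])) next
      add_protein(species, dom, paste0(species, "_", sanitise_domain(dom)))
    }
  }

  full_proteins <- proteins

  # ---- length outliers: truncated or extended copies ---------------------
  single_ids <- architectures$seq_id[!grepl("+", architectures$architecture, fixed = TRUE)]
  n_out <- round(config$outlier_fraction * nrow(proteins))
  outlier_ids <- if (n_out > 0) sort(sample(single_ids, n_out)) else character()
  for (k in seq_along(outlier_ids)) {
    pid <- outlier_ids[k]
    i <- match(pid, proteins$id)
    L <- nchar(proteins$residues[i])
    res <- if (k %% 2 == 1) {
      substr(proteins$residues[i], 1, floor(0.4 * L)) # truncated
    } else {
      paste0(proteins$residues[i], substr(proteins$residues[i], 1, ceiling(0.6 * L)))
    }
    proteins$residues[i] <- res
    h <- which(hits$seq_id == pid)
    hits$env_end[h] <- nchar(res)
    hits$bit_score[h] <- hits$bit_score[h] * min(1, nchar(res) / L)
  }

  # ---- split fragments sharing a parent_id -------------------------------
  hits$parent_id <- NA_character_
  n_frag <- round(config$fragment_fraction * nrow(full_proteins))
  frag_pool <- setdiff(single_ids, outlier_ids)
  fragment_parents <- if (n_frag > 0) sort(sample(frag_pool, n_frag)) else character()
  for (pid in fragment_parents) {
    i <- match(pid, proteins$id)
    res <- proteins$residues[i]
    L <- nchar(res)
    cut1 <- ceiling(0.55 * L)
    cut2 <- floor(0.45 * L) + 1
    f1 <- substr(res, 1, cut1)
    f2 <- substr(res, cut2, L)
    h <- which(hits$seq_id == pid)
    dom <- hits$domain[h[1]]
    score <- hits$bit_score[h[1]]
    proteins <- bind_rows(
      proteins[-i, , drop = FALSE],
      tibble(
        id = paste0(pid, ".f", 1:2), description = "",
        residues = c(f1, f2)
      )
    )
    hits <- bind_rows(
      hits[-h, , drop = FALSE],
      tibble(
        seq_id = paste0(pid, ".f", 1:2), domain = dom,
        env_start = 1L, env_end = c(nchar(f1), nchar(f2)),
        bit_score = score * c(0.55, 0.55), e_value = 0,
        parent_id = pid
      )
    )
    owner[paste0(pid, ".f1")] <- owner[[pid]]
    owner[paste0(pid, ".f2")] <- owner[[pid]]
  }

  proteins <- arrange(proteins, .data$id)
  hits <- arrange(hits, .data$seq_id, .data$env_start)
  scores <- select(hits, "seq_id", "domain", "bit_score")

  sp_row <- match(owner[names(owner)], species_tax$seq_id)
  taxonomy <- tibble(
    seq_id = names(owner),
    cell_domain = species_tax$cell_domain[sp_row],
    group = species_tax$group[sp_row],
    species = species_tax$species[sp_row]
  )
  taxonomy <- arrange(taxonomy, .data$seq_id)

  all_events <- config$hgt_events
  recipient_species <- unlist(lapply(all_events, `[[`, "recipients"))
  donor_species <- vapply(all_events, `[[`, character(1), "donor_species")
  donor_groups <- species_tax$group[match(donor_species, species_tax$seq_id)]

  dataset <- list(
    proteins = proteins,
    full_proteins = full_proteins,
    taxonomy = taxonomy,
    hits = hits,
    scores = scores,
    truth = list(
      species_tree = st$tree,
      species_taxonomy = species_tax,
      root_sequences = root_seqs,
      tip_sequences = tipseqs,
      recipient_species = recipient_species,
      recipient_protein_ids = paste0(recipient_species, "_fused"),
      donor_species = donor_species,
      donor_clade_tips = species_tax$seq_id[species_tax$group %in% donor_groups],
      architectures = arrange(architectures, .data$seq_id),
      outlier_ids = outlier_ids,
      fragment_parent_ids = fragment_parents
    )
  )
  if (!is.null(out_dir)) write_dataset(dataset, out_dir)
  dataset
}

write_dataset <- function(dataset, out_dir) {
  dir.create(file.path(out_dir, "truth", "alignments"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(dataset$proteins, file.path(out_dir, "proteins.fasta"))
  write_fasta(dataset$full_proteins, file.path(out_dir, "full_proteins.fasta"))
  readr::write_tsv(dataset$taxonomy, file.path(out_dir, "taxonomy.tsv"))
  readr::write_tsv(dataset$hits, file.path(out_dir, "hits.tsv"))
  readr::write_tsv(dataset$scores, file.path(out_dir, "scores.tsv"))
  write_newick(dataset$truth$species_tree, file.path(out_dir, "truth", "species_tree.nwk"))
  readr::write_tsv(
    dataset$truth$architectures,
    file.path(out_dir, "truth", "architectures.tsv")
  )
  writeLines(
    dataset$truth$recipient_protein_ids,
    file.path(out_dir, "truth", "recipients.txt")
  )
  writeLines(dataset$truth$outlier_ids, file.path(out_dir, "truth", "outliers.txt"))
  writeLines(
    dataset$truth$fragment_parent_ids,
    file.path(out_dir, "truth", "fragments.txt")
  )
  for (dom in names(dataset$truth$tip_sequences)) {
    s <- dataset$truth$tip_sequences[[dom]]
    write_fasta(
      tibble(id = names(s), description = "", residues = unname(s)),
      file.path(out_dir, "truth", "alignments", paste0(sanitise_domain(dom), ".fasta"))
    )
  }
  invisible(out_dir)
}

#' Extract one domain family from a dataset
#'
#' Pulls the envelope subsequence of every hit of `domain` out of the
#' protein records, giving the per-family record set the curation and tree
#' stages operate on.
#'
#' @param dataset A [build_dataset()] result.
#' @param domain Domain name.
#' @return A list: `records` (tibble `id`, `description`, `residues`,
#'   `bit_score`), `hits` (the hit rows of the family).
#' @export
family_records <- function(dataset, domain) {
  h <- dataset$hits[dataset$hits$domain == domain, , drop = FALSE]
  if (nrow(h) == 0) abort(paste0("no hits for domain '", domain, "'"))
  res <- dataset$proteins$residues[match(h$seq_id, dataset$proteins$id)]
  records <- tibble(
    id = h$seq_id,
    description = "",
    residues = substr(res, h$env_start, h$env_end),
    bit_score = h$bit_score
  )
  list(records = records, hits = h)
}

#' Synthetic absorbance spectrum of an acetone extract
#'
#' A Gaussian absorption band centred at the beta-carotene read wavelength
#' on a flat baseline, sampled every 0.5 nm from 400 to 800 nm. Useful for
#' round-trip tests of the quantification: after zeroing at 600 nm, the
#' absorbance recovered at the band centre is `peak_absorbance` up to the
#' (negligible) band tail at the baseline wavelength.
#'
#' @param peak_absorbance Band height above baseline at `centre_nm`.
#' @param baseline Constant baseline absorbance.
#' @param centre_nm Band centre (default 454 nm).
#' @param width_nm Gaussian standard deviation (default 30 nm).
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Optional seed for the noise.
#' @return A spectrum tibble of class `caro_spectrum`.
#' @export
simulate_spectrum <- function(peak_absorbance = 0.134, baseline = 0.02,
                              centre_nm = 454, width_nm = 30,
                              noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  wl <- seq(400, 800, by = 0.5)
  a <- baseline + peak_absorbance * exp(-(wl - centre_nm)^2 / (2 * width_nm^2))
  if (noise_sd > 0) a <- a + stats::rnorm(length(wl), 0, noise_sd)
  validate_spectrum(tibble(wavelength_nm = wl, absorbance = a))
}
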