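# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (exhaustive enumeration, brute-force scans) so they
# share no code with the implementation they check.

# All shortest s-t paths by BFS layering + backward DFS over the distance DAG.
all_shortest_paths <- function(adj, s, t) {
  nodes <- names(adj)
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[s] <- 0
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- unique(nxt)
  }
  if (is.infinite(dist[t])) return(list())
  walk <- function(v) {
    if (v == s) return(list(s))
    preds <- adj[[v]][dist[adj[[v]]] == dist[v] - 1]
    unlist(lapply(preds, function(p) {
      lapply(walk(p), function(path) c(path, v))
    }), recursive = FALSE)
  }
  walk(t)
}

# Unnormalized node betweenness, endpoints excluded, each unordered pair once.
brute_betweenness <- function(nodes, edges) {
  adj <- stats::setNames(lapply(nodes, function(v) {
    unique(c(edges$b[edges$a == v], edges$a[edges$b == v]))
  }), nodes)
  bw <- stats::setNames(rep(0, length(nodes)), nodes)
  if (length(nodes) < 2) return(bw)
  for (pair in utils::combn(nodes, 2, simplify = FALSE)) {
    paths <- all_shortest_paths(adj, pair[1], pair[2])
    if (length(paths) == 0) next
    inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(inner) == 0) next
    tab <- table(inner)
    bw[names(tab)] <- bw[names(tab)] + as.numeric(tab) / length(paths)
  }
  bw
}

# Random simple graph over n nodes with edge probability p.
random_graph_edges <- function(n, p) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  tibble::tibble(a = pairs[1, keep], b = pairs[2, keep],
                 score = rep(1, sum(keep)))
}

# Brute-force normalization of a scored edge list (oracle for build_network).
brute_normalize_edges <- function(edges, min_score) {
  seen <- list()
  for (i in seq_len(nrow(edges))) {
    if (edges$score[i] < min_score || edges$a[i] == edges$b[i]) next
    key <- paste(sort(c(edges$a[i], edges$b[i])), collapse = "\r")
    if (is.null(seen[[key]]) || seen[[key]] < edges$score[i]) {
      seen[[key]] <- edges$score[i]
    }
  }
  if (length(seen) == 0) {
    return(tibble::tibble(a = character(), b = character(), score = double()))
  }
  parts <- strsplit(names(seen), "\r", fixed = TRUE)
  out <- tibble::tibble(a = vapply(parts, `[`, "", 1),
                        b = vapply(parts, `[`, "", 2),
                        score = unlist(seen, use.names = FALSE))
  out[order(out$a, out$b), ]
}

# Build a genotype_matrix from a compact description, for classifier tests.
# geno: character matrix sites x samples ("-" or NA for missing).
make_gm <- function(geno, samples, ref, alt, chrom = "chr1",
                    pos = NULL, qual = NA_real_, gene = NULL) {
  geno[geno == "-"] <- NA_character_
  n <- nrow(geno)
  sites <- tibble::tibble(
    chrom = rep(chrom, n),
    pos = if (is.null(pos)) seq_len(n) * 100L else as.integer(pos),
    ref = ref, alt = alt, qual = rep(qual, length.out = n)
  )
  if (!is.null(gene)) sites$gene <- gene
  colnames(geno) <- samples
  structure(list(sites = sites, samples = samples, geno = geno),
            class = "genotype_matrix")
}

two_group_map <- function(n_high, n_low) {
  tibble::tibble(
    sample_id = c(sprintf("H%d", seq_len(n_high)), sprintf("L%d", seq_len(n_low))),
    group = rep(c("HIGH", "LOW"), c(n_high, n_low))
  )
}

# Small cohort config used wherever many seeds are replayed.
small_cohort_config <- function(seed, missing_rate = 0) {
  synthetic_config(
    seed = seed,
    genome_length = 8000,
    genes_per_genome = 8,
    sites_per_category = c(FIXED_HIGH_VARIABLE_LOW = 3,
                           FIXED_LOW_VARIABLE_HIGH = 3,
                           FIXED_BOTH_CONCORDANT = 1,
                           FIXED_BOTH_DISCORDANT = 1,
                           VARIABLE_BOTH = 2),
    missing_rate = missing_rate
  )
}
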