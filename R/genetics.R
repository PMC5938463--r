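round_half_up <- function(x, digits = 2L) {
  # R's round() is half-even; divergence percentages are reported half-up
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Read aligned haplotype reference sequences from FASTA
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @return Named character vector of upper-case sequences.
#' @export
read_haplotypes <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(set)), names(set))
}

#' Write haplotype sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Pairwise sequence divergence
#'
#' Counts mismatching sites between two aligned sequences of equal length.
#' Sites where either sequence carries an ambiguous or gap symbol
#' (`N`, `-`, `?`) are excluded from both the numerator and the denominator.
#' The percentage is `100 * differences / compared`, reported half-up to two
#' decimals (e.g. 6 of 481 sites is 1.25%).
#'
#' @param seq_a,seq_b character scalars (aligned, equal length).
#' @return List with `site_differences`, `sites_compared`, `percent`.
#' @export
pairwise_divergence <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1L]]
  b <- strsplit(toupper(seq_b), "")[[1L]]
  if (length(a) != length(b))
    stop("alignment error: sequences have different lengths")
  ok <- !(a %in% c("N", "-", "?")) & !(b %in% c("N", "-", "?"))
  diffs <- sum(a[ok] != b[ok])
  compared <- sum(ok)
  list(site_differences = diffs, sites_compared = compared,
       percent = round_half_up(100 * diffs / compared, 2L))
}

#' Assign a query sequence to the nearest haplotype reference
#'
#' Nearest neighbour by site differences ([pairwise_divergence()]). An exact
#' match is reported with distance 0; a non-zero distance flags a novel
#' variant with a suggested derived name; equidistant references yield an
#' ambiguous assignment listing all minima.
#'
#' @param query character scalar, same aligned length as the references.
#' @param references named character vector of reference sequences.
#' @return List with `name`, `distance`, `ambiguous`, `candidates`,
#'   `novel`, `suggested_name` (`NA` unless novel and unambiguous).
#' @export
assign_haplotype <- function(query, references) {
  if (length(references) == 0L)
    stop("configuration error: empty reference set")
  d <- vapply(references, function(r)
    pairwise_divergence(query, r)$site_differences, numeric(1))
  dmin <- min(d)
  hits <- names(d)[d == dmin]
  ambiguous <- length(hits) > 1L
  novel <- dmin > 0
  list(name = hits[1L], distance = dmin, ambiguous = ambiguous,
       candidates = hits, novel = novel,
       suggested_name = if (novel && !ambiguous) paste0(hits[1L], "2")
                        else NA_character_)
}

#' Encode per-locus SNP calls as a dosage-agnostic two-character string
#'
#' Each locus contributes two positions, one per detected allelic state in
#' alphabetical order: a homozygous locus is written as two identical
#' characters (`"TT"`), a heterozygous locus as the sorted pair (`"AG"`),
#' and a missing locus as `"??"`. Allele dosage is deliberately not encoded
#' (presence/absence genotyping cannot distinguish e.g. AAG from AGG in
#' polyploids). Loci are concatenated in their given order.
#'
#' @param calls list (or character vector) of per-locus calls; each element
#'   is 1-2 allele symbols from `A,C,G,T` given as a vector (`c("A","G")`)
#'   or a string (`"A"`, `"A/G"`, `"AG"`); `"?"`, `""` or `NA` mark a
#'   missing locus.
#' @return Encoded string of length `2 * length(calls)`.
#' @export
encode_genotype <- function(calls) {
  enc <- vapply(calls, function(cl) {
    if (length(cl) == 1L && (is.na(cl) || cl %in% c("?", "", "?/?", "??")))
      return("??")
    al <- if (length(cl) > 1L) cl else strsplit(gsub("[/|]", "", cl), "")[[1L]]
    al <- toupper(al[nzchar(al)])
    if (any(al == "?")) return("??")
    if (!all(al %in% c("A", "C", "G", "T")))
      stop("invalid allele symbol in call: ", paste(cl, collapse = "/"))
    al <- sort(unique(al))
    if (length(al) > 2L)
      stop("ploidy-encoding error: more than two distinct alleles at a locus")
    if (length(al) == 1L) al <- c(al, al)
    paste(al, collapse = "")
  }, character(1))
  paste(enc, collapse = "")
}

#' Expand an encoded genotype back into per-locus calls
#'
#' Inverse of [encode_genotype()]: returns one call string per locus
#' (`"A"`, `"A/G"` or `"?"`).
#'
#' @param encoded encoded genotype string (even length).
#' @return Character vector of per-locus calls.
#' @export
decode_genotype <- function(encoded) {
  ch <- strsplit(encoded, "")[[1L]]
  if (length(ch) %% 2L != 0L) stop("encoded string must have even length")
  n <- length(ch) / 2L
  vapply(seq_len(n), function(j) {
    p <- ch[c(2L * j - 1L, 2L * j)]
    if (any(p == "?")) "?"
    else if (p[1L] == p[2L]) p[1L]
    else paste(p, collapse = "/")
  }, character(1))
}

#' Collapse encoded individuals into multilocus genotypes
#'
#' Individuals sharing an identical encoded string (the missing symbol is
#' treated as a distinct literal, so genotypes that differ only in their
#' missing loci remain distinct) collapse into one multilocus genotype.
#' Genotypes are numbered by descending abundance, ties broken by first
#' appearance; fixed versus variable loci across the cohort are reported
#' (a locus is variable when more than one distinct non-missing pair
#' occurs).
#'
#' @param encoded character vector of encoded genotype strings (equal
#'   lengths).
#' @param ids optional individual identifiers.
#' @param loci optional locus names (length `nchar/2`).
#' @return Object of class `mlg_set`: list with `genotypes` (data frame:
#'   `genotype_id`, `encoded`, `count`), `assignments` (per individual),
#'   `variable_loci`, `fixed_loci`, `loci`.
#' @export
collapse_mlg <- function(encoded, ids = NULL, loci = NULL) {
  if (length(unique(nchar(encoded))) != 1L)
    stop("encoded strings must have equal length")
  if (is.null(ids)) ids <- sprintf("ind_%d", seq_along(encoded))
  first_seen <- match(unique(encoded), encoded)
  uniq <- unique(encoded)
  cnt <- as.vector(table(factor(encoded, levels = uniq)))
  ord <- order(-cnt, first_seen)
  uniq <- uniq[ord]; cnt <- cnt[ord]
  gid <- seq_along(uniq)
  n_loci <- nchar(encoded[1L]) / 2L
  if (is.null(loci)) loci <- sprintf("locus_%d", seq_len(n_loci))
  pair_at <- function(s, j) substr(s, 2L * j - 1L, 2L * j)
  variable <- vapply(seq_len(n_loci), function(j) {
    pairs <- vapply(encoded, pair_at, character(1), j = j)
    length(unique(pairs[pairs != "??"])) > 1L
  }, logical(1))
  structure(
    list(genotypes = data.frame(genotype_id = gid, encoded = uniq,
                                count = cnt),
         assignments = data.frame(id = ids, encoded = encoded,
                                  genotype_id = gid[match(encoded, uniq)]),
         variable_loci = loci[variable], fixed_loci = loci[!variable],
         loci = loci),
    class = "mlg_set")
}

#' @export
print.mlg_set <- function(x, ...) {
  cat(sprintf("<mlg_set> %d individuals, %d genotypes; %d/%d loci variable\n",
              nrow(x$assignments), nrow(x$genotypes),
              length(x$variable_loci), length(x$loci)))
  invisible(x)
}

#' Substitution distance between two encoded genotypes
#'
#' Counts positions with unequal non-missing symbols; positions where
#' either genotype carries `?` are skipped (pairwise deletion). Under
#' pairwise deletion this is a pseudo-metric: symmetric with zero
#' self-distance, but the triangle inequality is not guaranteed, because
#' different pairs may be compared over different position sets.
#'
#' @param g_a,g_b encoded genotype strings of equal length.
#' @return Integer substitution count.
#' @export
mlg_distance <- function(g_a, g_b) {
  a <- strsplit(g_a, "")[[1L]]
  b <- strsplit(g_b, "")[[1L]]
  if (length(a) != length(b)) stop("encoded strings must have equal length")
  ok <- a != "?" & b != "?"
  sum(a[ok] != b[ok])
}

mlg_dist_matrix <- function(encoded) {
  n <- length(encoded)
  D <- matrix(0L, n, n)
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n))
      D[i, j] <- D[j, i] <- mlg_distance(encoded[i], encoded[j])
  D
}

# epsilon-relaxed minimum spanning network over a distance matrix.
# An edge of weight w is kept iff its endpoints are not connected using
# only edges of weight < w - epsilon; ties are processed in lexicographic
# (i, j) order, which together with the rule makes the result deterministic
# and order-of-ties independent.
msn_edges <- function(D, epsilon = 0) {
  n <- nrow(D)
  if (n <= 1L) return(data.frame(from = integer(), to = integer(),
                                 weight = numeric()))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[upper.tri(D)]
  ord <- order(w, pairs[, 1L], pairs[, 2L])
  pairs <- pairs[ord, , drop = FALSE]; w <- w[ord]
  comp_below <- function(maxw) {
    # components using accepted edges with weight < maxw
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (e in seq_len(nrow(acc))) {
      if (acc$weight[e] < maxw) {
        ri <- find(acc$from[e]); rj <- find(acc$to[e])
        if (ri != rj) parent[ri] <- rj
      }
    }
    vapply(seq_len(n), find, integer(1))
  }
  acc <- data.frame(from = integer(), to = integer(), weight = numeric())
  for (lev in unique(w)) {
    comp <- comp_below(lev - epsilon + 1e-9)
    sel <- which(w == lev)
    for (e in sel) {
      i <- pairs[e, 1L]; j <- pairs[e, 2L]
      if (comp[i] != comp[j])
        acc <- rbind(acc, data.frame(from = i, to = j, weight = lev))
    }
  }
  acc
}

# position-wise median of three encoded genotypes: majority symbol, ties
# (all three distinct) broken lexicographically ('?' sorts first)
median_vector <- function(a, b, c) {
  m <- rbind(strsplit(a, "")[[1L]], strsplit(b, "")[[1L]],
             strsplit(c, "")[[1L]])
  paste(apply(m, 2L, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    if (tb[1L] > 1L) names(tb)[1L] else sort(col)[1L]
  }), collapse = "")
}

#' Median-joining network of multilocus genotypes
#'
#' Bandelt-style construction: the epsilon-relaxed minimum spanning network
#' over the observed genotypes is computed from [mlg_distance()] distances;
#' consensus (median) vectors of connected triplets are then added greedily
#' whenever they shorten the total network length, and median vectors of
#' degree < 3 are removed on cleanup. Deterministic under fixed input order
#' with lexicographic tie-breaking on candidate links and median strings.
#'
#' @param genotypes encoded genotype strings (equal lengths); an `mlg_set`
#'   from [collapse_mlg()] is also accepted.
#' @param epsilon relaxation parameter (default 0: minimum spanning
#'   network).
#' @param counts optional per-genotype sample counts (carried to nodes).
#' @param labels optional node labels (default genotype numbers).
#' @param max_candidates cap on median candidates evaluated per round
#'   (lexicographic order); the search is exhaustive for the collapsed
#'   genotype sets (tens of nodes) this method is meant for.
#' @return Object of class `haplotype_network`: list with `nodes`
#'   (data frame: `node`, `label`, `encoded`, `type`, `count`), `edges`
#'   (`from`, `to`, `weight` in substitutions), `epsilon`.
#' @export
median_joining_network <- function(genotypes, epsilon = 0, counts = NULL,
                                   labels = NULL, max_candidates = 200L) {
  if (inherits(genotypes, "mlg_set")) {
    counts <- genotypes$genotypes$count
    labels <- as.character(genotypes$genotypes$genotype_id)
    genotypes <- genotypes$genotypes$encoded
  }
  if (length(unique(nchar(genotypes))) > 1L)
    stop("encoded strings must have equal length")
  if (is.null(labels)) labels <- as.character(seq_along(genotypes))
  if (is.null(counts)) counts <- rep(1L, length(genotypes))
  obs <- data.frame(label = labels, encoded = genotypes, type = "observed",
                    count = counts, stringsAsFactors = FALSE)
  if (nrow(obs) == 1L) {
    return(structure(list(
      nodes = cbind(node = 1L, obs),
      edges = data.frame(from = integer(), to = integer(),
                         weight = numeric()),
      epsilon = epsilon), class = "haplotype_network"))
  }
  nodes <- obs
  net_edges <- function(nd) msn_edges(mlg_dist_matrix(nd$encoded), epsilon)
  net_len <- function(ed) sum(ed$weight)
  edges <- net_edges(nodes)
  for (iter in seq_len(200L)) {
    cur_len <- net_len(edges)
    adj <- matrix(FALSE, nrow(nodes), nrow(nodes))
    adj[cbind(edges$from, edges$to)] <- TRUE
    adj <- adj | t(adj)
    cands <- character(0)
    nn <- nrow(nodes)
    for (u in seq_len(nn - 2L)) for (v in seq((u + 1L), nn - 1L))
      for (w in seq((v + 1L), nn)) {
        if (adj[u, v] + adj[u, w] + adj[v, w] >= 2L) {
          m <- median_vector(nodes$encoded[u], nodes$encoded[v],
                             nodes$encoded[w])
          if (!(m %in% nodes$encoded)) cands <- c(cands, m)
        }
      }
    cands <- sort(unique(cands))
    if (!length(cands)) break
    if (length(cands) > max_candidates) cands <- cands[seq_len(max_candidates)]
    best <- NULL; best_len <- cur_len
    for (m in cands) {
      trial <- rbind(nodes, data.frame(label = NA, encoded = m,
                                       type = "median", count = 0L))
      len <- net_len(net_edges(trial))
      if (len < best_len - 1e-9) { best_len <- len; best <- m }
    }
    if (is.null(best)) break
    nodes <- rbind(nodes,
                   data.frame(label = sprintf("mv%d",
                                              sum(nodes$type == "median") + 1L),
                              encoded = best, type = "median", count = 0L))
    edges <- net_edges(nodes)
  }
  # cleanup: drop median vectors of degree < 3, iteratively
  repeat {
    deg <- tabulate(c(edges$from, edges$to), nbins = nrow(nodes))
    drop <- which(nodes$type == "median" & deg < 3L)
    if (!length(drop)) break
    nodes <- nodes[-drop, , drop = FALSE]
    edges <- net_edges(nodes)
  }
  nodes <- cbind(node = seq_len(nrow(nodes)), nodes)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, epsilon = epsilon),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype_network> %d observed + %d median nodes, %d edges (epsilon = %g)\n",
              sum(x$nodes$type == "observed"),
              sum(x$nodes$type == "median"), nrow(x$edges), x$epsilon))
  invisible(x)
}

#' Convert a haplotype network to an igraph object
#'
#' @param network a `haplotype_network`.
#' @return An undirected [igraph::graph_from_data_frame()] graph with
#'   `weight` edge attributes and `label`, `type`, `count`, `encoded`
#'   vertex attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "haplotype_network"))
  v <- network$nodes
  e <- network$edges
  igraph::graph_from_data_frame(
    data.frame(from = v$node[e$from], to = v$node[e$to], weight = e$weight),
    directed = FALSE,
    vertices = data.frame(name = v$node, label = v$label, type = v$type,
                          count = v$count, encoded = v$encoded))
}

#' Write a haplotype network as edge-list CSV and GraphML
#'
#' @param network a `haplotype_network`.
#' @param edge_csv path for the edge list (`node_a, node_b, type_a, type_b,
#'   weight`); `NULL` to skip.
#' @param graphml path for GraphML output (via igraph); `NULL` to skip.
#' @return Invisibly, the network.
#' @export
write_network <- function(network, edge_csv = NULL, graphml = NULL) {
  if (!is.null(edge_csv)) {
    v <- network$nodes; e <- network$edges
    df <- data.frame(node_a = v$label[e$from], node_b = v$label[e$to],
                     type_a = v$type[e$from], type_b = v$type[e$to],
                     weight = e$weight)
    write.csv(df, edge_csv, row.names = FALSE)
  }
  if (!is.null(graphml))
    igraph::write_graph(as_igraph(network), graphml, format = "graphml")
  invisible(network)
}

#' Read a per-specimen genotype call table
#'
#' Expects columns `specimen_id`, `site_id`, then one column per locus with
#' calls like `"A"`, `"A/G"` or `"?"` (empty = missing).
#'
#' @param path CSV path.
#' @return Data frame; locus columns are everything after the first two.
#' @export
read_genotype_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = "character")
  if (!all(c("specimen_id", "site_id") %in% names(df)[1:2]))
    stop("genotype CSV must start with specimen_id, site_id columns")
  df
}

#' Encode every row of a genotype call table
#'
#' @param geno data frame from [read_genotype_csv()].
#' @return Named character vector of encoded strings (names = specimen ids).
#' @export
encode_genotype_table <- function(geno) {
  loci <- setdiff(names(geno), c("specimen_id", "site_id"))
  enc <- vapply(seq_len(nrow(geno)), function(i)
    encode_genotype(as.list(unlist(geno[i, loci], use.names = FALSE))),
    character(1))
  setNames(enc, geno$specimen_id)
}
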