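# Random genome layer: fixed-length random genes, a TF network derived by
# sequence matching, and the aggregate regulatory drive per gene.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Generate a random genome
#'
#' Assembles a genome from `n_genes` random genes of fixed length. Each gene
#' consists of a regulatory region (`l_reg` bases, carrying `l_reg / 200`
#' cooperative nucleosomes), a promoter (`l_pro`) and a coding sequence
#' (`l_cod`), all drawn uniformly from the four-letter base alphabet. The
#' coding sequence deterministically defines the gene's TF recognition word
#' and regulatory sign (see [build_tf_network()]); the promoter's GC content
#' defines the gene's basal transcriptional drive. Generation is fully
#' reproducible under R's random seed.
#'
#' @param n_genes number of genes (>= 1).
#' @param lengths named integer vector/list with `l_reg` (>= 200), `l_pro`
#'   and `l_cod` (>= 1 each, `l_cod` >= `word_length`).
#' @param word_length length of the TF recognition word (default 8).
#' @return An object of class `genome`: list with `genes` (list of per-gene
#'   lists `reg_seq`, `pro_seq`, `cod_seq`, `index`), `lengths`,
#'   `n_nucleosomes`, `word_length`.
#' @examples
#' set.seed(1)
#' g <- generate_genome(5)
#' g$n_nucleosomes  # l_reg / 200
#' @export
generate_genome <- function(n_genes,
                            lengths = c(l_reg = 4000L, l_pro = 500L, l_cod = 900L),
                            word_length = 8L) {
  lengths <- as.list(lengths)
  stopifnot(n_genes >= 1L,
            lengths$l_reg >= 200L, lengths$l_reg %% 200L == 0L,
            lengths$l_pro >= 1L, lengths$l_cod >= word_length)
  rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")
  genes <- lapply(seq_len(n_genes), function(i) {
    list(reg_seq = rand_seq(lengths$l_reg),
         pro_seq = rand_seq(lengths$l_pro),
         cod_seq = rand_seq(lengths$l_cod),
         index = i)
  })
  structure(list(genes = genes,
                 lengths = lengths,
                 n_nucleosomes = as.integer(lengths$l_reg / 200L),
                 word_length = as.integer(word_length)),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("Random genome: %d genes (reg %d / pro %d / cod %d bases, %d nucleosomes)\n",
              length(x$genes), x$lengths$l_reg, x$lengths$l_pro,
              x$lengths$l_cod, x$n_nucleosomes))
  invisible(x)
}

#' TF recognition word of a gene
#'
#' Deterministic transformation of the coding sequence into the recognition
#' word bound by the encoded TF: the base complement of the first
#' `word_length` coding bases. The regulatory sign of the TF is the parity of
#' the number of G/C bases in the word: even = activator, odd = repressor.
#'
#' @param cod_seq coding sequence (single string).
#' @param word_length word length.
#' @return A list with `word` (string) and `sign` (+1 activator / -1 repressor).
#' @export
tf_recognition <- function(cod_seq, word_length = 8L) {
  head_bases <- strsplit(substr(cod_seq, 1L, word_length), "")[[1]]
  word <- paste(unname(COMPLEMENT[head_bases]), collapse = "")
  gc <- sum(head_bases %in% c("G", "C"))
  list(word = word, sign = if (gc %% 2L == 0L) 1L else -1L)
}

count_occurrences <- function(word, seq) {
  # overlapping occurrences of `word` in `seq`
  n <- 0L
  start <- 1L
  repeat {
    hit <- regexpr(word, substr(seq, start, nchar(seq)), fixed = TRUE)
    if (hit == -1L) break
    n <- n + 1L
    start <- start + hit # advance one base past the match start -> overlapping
  }
  n
}

#' Build the TF regulatory network of a genome
#'
#' For every ordered gene pair (i, j), counts the (overlapping) occurrences of
#' gene i's TF recognition word in gene j's regulatory region. A nonzero
#' count creates a directed edge i -> j with weight equal to the occurrence
#' multiplicity and the sign of gene i's TF. The construction is a pure
#' function of the genome, so regenerating the network yields an identical
#' graph.
#'
#' @param g a [generate_genome()] object.
#' @return An object of class `tf_network`: list with `edges` (data.frame
#'   `from`, `to`, `weight`, `sign`), `words` (per-gene recognition word),
#'   `signs`, `basal` (per-gene basal drive derived from promoter GC content)
#'   and `n_genes`.
#' @export
build_tf_network <- function(g) {
  stopifnot(inherits(g, "genome"))
  n <- length(g$genes)
  rec <- lapply(g$genes, function(gene) tf_recognition(gene$cod_seq, g$word_length))
  words <- vapply(rec, `[[`, character(1), "word")
  signs <- vapply(rec, `[[`, integer(1), "sign")
  from <- integer(0); to <- integer(0); weight <- integer(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      cnt <- count_occurrences(words[i], g$genes[[j]]$reg_seq)
      if (cnt > 0L) {
        from <- c(from, i); to <- c(to, j); weight <- c(weight, cnt)
      }
    }
  }
  basal <- vapply(g$genes, function(gene) {
    b <- strsplit(gene$pro_seq, "")[[1]]
    mean(b %in% c("G", "C"))
  }, numeric(1))
  structure(list(
    edges = data.frame(from = from, to = to, weight = weight,
                       sign = signs[from]),
    words = words, signs = signs, basal = basal, n_genes = n
  ), class = "tf_network")
}

#' @export
print.tf_network <- function(x, ...) {
  cat(sprintf("TF network: %d genes, %d edges (%d activating, %d repressing)\n",
              x$n_genes, nrow(x$edges), sum(x$edges$sign > 0),
              sum(x$edges$sign < 0)))
  invisible(x)
}

#' Aggregate TF-network drive on a gene
#'
#' Sums activating minus repressing inputs from bound TFs (weighted by
#' binding multiplicity and the upstream transcription levels) on top of the
#' gene's basal drive, and passes the total through a saturating logistic
#' function. The result is monotone non-decreasing in every upstream
#' activating transcription level and bounded in (0, 1).
#'
#' The basal drive of gene j is `basal_gain * (GC_j - 0.5)` where `GC_j` is
#' the promoter GC content, which spreads genes over the whole drive range
#' and thereby seeds the split into highly and weakly transcribed genes.
#'
#' @param gene_index index of the target gene.
#' @param tf_levels non-negative per-gene transcription levels.
#' @param net a [build_tf_network()] object.
#' @param basal_gain,input_scale coefficients of the aggregation rule.
#' @return The regulatory drive in (0, 1).
#' @export
tf_regulatory_input <- function(gene_index, tf_levels, net,
                                basal_gain = 30, input_scale = 1) {
  stopifnot(inherits(net, "tf_network"), all(tf_levels >= 0),
            length(tf_levels) == net$n_genes,
            gene_index >= 1L, gene_index <= net$n_genes)
  e <- net$edges[net$edges$to == gene_index, , drop = FALSE]
  u <- basal_gain * (net$basal[gene_index] - 0.5)
  if (nrow(e)) u <- u + input_scale * sum(e$sign * e$weight * tf_levels[e$from])
  plogis(u)
}

# Vectorised drive for all genes across all cells. t_mat: genes x cells
# matrix of transcription levels. Returns genes x cells matrix of drives.
tf_drive_matrix <- function(t_mat, net, basal_gain = 30, input_scale = 1) {
  n <- net$n_genes
  w <- matrix(0, n, n)
  if (nrow(net$edges))
    w[cbind(net$edges$from, net$edges$to)] <- net$edges$sign * net$edges$weight
  u <- basal_gain * (net$basal - 0.5) + input_scale * crossprod(w, t_mat)
  plogis(u)
}

#' Write a genome as plain FASTA
#'
#' One record per gene region with IDs `gene<k>|reg`, `gene<k>|pro`,
#' `gene<k>|cod`.
#'
#' @param g a genome.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(g, path) {
  stopifnot(inherits(g, "genome"))
  con <- file(path, "w")
  on.exit(close(con))
  for (gene in g$genes) {
    for (region in c("reg", "pro", "cod")) {
      writeLines(sprintf(">gene%d|%s", gene$index, region), con)
      s <- gene[[paste0(region, "_seq")]]
      starts <- seq(1L, nchar(s), by = 70L)
      writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Read a genome from FASTA written by [write_genome_fasta()]
#' @param path FASTA file path.
#' @param word_length recognition word length.
#' @return A `genome` object.
#' @export
read_genome_fasta <- function(path, word_length = 8L) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  ids <- sub("^>", "", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 paste, character(1), collapse = "")
  names(seqs) <- ids
  gene_ids <- unique(sub("\\|.*$", "", ids))
  genes <- lapply(seq_along(gene_ids), function(i) {
    gid <- gene_ids[i]
    list(reg_seq = unname(seqs[paste0(gid, "|reg")]),
         pro_seq = unname(seqs[paste0(gid, "|pro")]),
         cod_seq = unname(seqs[paste0(gid, "|cod")]),
         index = i)
  })
  lengths <- list(l_reg = nchar(genes[[1]]$reg_seq),
                  l_pro = nchar(genes[[1]]$pro_seq),
                  l_cod = nchar(genes[[1]]$cod_seq))
  structure(list(genes = genes, lengths = lengths,
                 n_nucleosomes = as.integer(lengths$l_reg / 200L),
                 word_length = as.integer(word_length)),
            class = "genome")
}

#' Write the TF network edge list as a tab-separated table
#' @param net a `tf_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tf_edges <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
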