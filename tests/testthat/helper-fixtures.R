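# Hand-built fixtures, constructed in code at test time.

# A small annotation: one +strand gene with a cassette exon and an intronic
# snoRNA, one -strand gene, and one snoRNA without a valid host.
#
# GENEA (+, chr1): -201 protein_coding exons [100,200) [300,400) [500,600)
#   [700,800); -202 protein_coding skips exon 3; -203 lncRNA exons [100,200)
#   [700,800). SNOA [420,480) sits in intron 2 of -201.
# GENEB (-, chr1): -201 protein_coding exons [2000,2100) [2300,2400)
#   [2600,2700). SNOB [2450,2520) sits in its middle intron.
# SNOC [5000,5060) (+) has no containing gene.
make_ann <- function() {
  genes <- data.frame(
    gene_id = c("GENEA", "GENEB"),
    biotype = "protein_coding",
    chrom = "chr1",
    start = c(100L, 2000L), end = c(800L, 2700L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  transcripts <- data.frame(
    transcript_id = c("GENEA-201", "GENEA-202", "GENEA-203", "GENEB-201"),
    transcript_name = c("GENEA-201", "GENEA-202", "GENEA-203", "GENEB-201"),
    gene_id = c("GENEA", "GENEA", "GENEA", "GENEB"),
    biotype = c("protein_coding", "protein_coding", "lncRNA",
                "protein_coding"),
    chrom = "chr1",
    start = c(100L, 100L, 100L, 2000L), end = c(800L, 800L, 800L, 2700L),
    strand = c("+", "+", "+", "-"), stringsAsFactors = FALSE)
  transcripts$name_number <- c(201L, 202L, 203L, 201L)
  exons <- data.frame(
    transcript_id = c(rep("GENEA-201", 4), rep("GENEA-202", 3),
                      rep("GENEA-203", 2), rep("GENEB-201", 3)),
    gene_id = c(rep("GENEA", 9), rep("GENEB", 3)),
    chrom = "chr1",
    start = c(100L, 300L, 500L, 700L,  100L, 300L, 700L,  100L, 700L,
              2000L, 2300L, 2600L),
    end = c(200L, 400L, 600L, 800L,  200L, 400L, 800L,  200L, 800L,
            2100L, 2400L, 2700L),
    strand = c(rep("+", 9), rep("-", 3)), stringsAsFactors = FALSE)
  snornas <- data.frame(
    sno_id = c("SNOA", "SNOB", "SNOC"),
    box_type = c("CD", "HACA", "CD"),
    chrom = "chr1",
    start = c(420L, 2450L, 5000L), end = c(480L, 2520L, 5060L),
    strand = c("+", "-", "+"),
    host_gene_id = c("GENEA", "GENEB", NA), stringsAsFactors = FALSE)
  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 snornas = snornas),
            class = "snohost_annotation")
}

# one chimeric read row
read_row <- function(s1, e1, s2, e2, dataset = "P0", support = 1L,
                     chrom = "chr1", strand1 = "+", strand2 = "+") {
  data.frame(chrom1 = chrom, start1 = s1, end1 = e1, strand1 = strand1,
             chrom2 = chrom, start2 = s2, end2 = e2, strand2 = strand2,
             dataset_id = dataset, support = support,
             stringsAsFactors = FALSE)
}

# write a bedGraph (0-based half-open) and return a snohost_track
make_track <- function(starts, ends, scores, chrom = "chr1") {
  path <- tempfile(fileext = ".bedgraph")
  write.table(data.frame(chrom, starts, ends, scores), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  read_track(path)
}

# brute-force transitive-closure clustering oracle for the merge predicate
# (left arms overlap >= 1 nt AND right arms overlap >= 1 nt, same chrom and
# strand per arm); returns a vector of cluster labels
oracle_clusters <- function(reads) {
  n <- nrow(reads)
  link <- matrix(FALSE, n, n)
  ov <- function(i, j, side) {
    c1 <- reads[[paste0("chrom", side)]]; s <- reads[[paste0("start", side)]]
    e <- reads[[paste0("end", side)]]; st <- reads[[paste0("strand", side)]]
    c1[i] == c1[j] && st[i] == st[j] && min(e[i], e[j]) - max(s[i], s[j]) > 0
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    link[i, j] <- ov(i, j, 1) && ov(i, j, 2)
  }
  # transitive closure by repeated boolean propagation
  repeat {
    nxt <- (link %*% link) > 0 | link
    if (identical(nxt, link)) break
    link <- nxt
  }
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      cl <- cl + 1L
      labels[which(link[i, ])] <- cl
    }
  }
  labels
}

# random small chimera set with frequent overlaps, for merge-oracle tests
random_read_set <- function(n) {
  strand <- sample(c("+", "-"), 1)
  ls <- sample(0:60, n, replace = TRUE)
  ll <- sample(5:15, n, replace = TRUE)
  rs <- sample(100:160, n, replace = TRUE)
  rl <- sample(5:15, n, replace = TRUE)
  data.frame(chrom1 = "c1", start1 = ls, end1 = ls + ll, strand1 = strand,
             chrom2 = "c1", start2 = rs, end2 = rs + rl, strand2 = strand,
             dataset_id = sample(c("P0", "L1", "S2"), n, replace = TRUE),
             support = sample(1:3, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
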