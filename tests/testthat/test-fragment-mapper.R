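test_that("every reference k-mer is findable at its own position, including across the origin", {
  set.seed(13)
  seqn <- paste0(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  seqn <- paste0("ATG", seqn, "TAA")  # 66 nt toy circle
  p <- plasmid_map("mini", seqn, cds_start = 0L, cds_aa_length = 1L)
  idx <- index_reference(p, k = 12L)
  doubled <- paste0(seqn, seqn)
  for (pos in 0:(p$length - 1L)) {
    kmer <- substr(doubled, pos + 1L, pos + 12L)
    expect_true(pos %in% fragmap:::kmer_hits(idx, kmer))
  }
  expect_identical(fragmap:::kmer_hits(idx, strrep("A", 12L)), integer(0))
  expect_error(index_reference(p, k = 100L), "smaller")
})

test_that("error-free reads map back to their true location", {
  p <- toy_plasmid(orf_aa = 400L, total_len = 3000L, cds_start = 1000L)
  idx <- index_reference(p)
  params <- alignment_params()
  set.seed(21)
  for (rep in 1:30) {
    pos <- sample(0:2999, 1)
    read <- plasmid_subseq(p, pos, 150L)
    m <- map_read(read, idx, params)
    expect_identical(m$pos, pos)
    expect_identical(m$strand, "+")
    expect_identical(m$nm, 0L)
    mrc <- map_read(revcomp(read), idx, params)
    expect_identical(mrc$pos, pos)
    expect_identical(mrc$strand, "-")
  }
})

test_that("reads exceeding the mismatch budget are unmapped", {
  p <- toy_plasmid(orf_aa = 400L, total_len = 3000L, cds_start = 1000L)
  idx <- index_reference(p)
  params <- alignment_params(max_mismatches = 3L)
  read <- plasmid_subseq(p, 500L, 150L)
  mutate <- function(s, at) {
    ch <- strsplit(s, "")[[1]]
    ch[at] <- vapply(ch[at], function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                     character(1))
    paste0(ch, collapse = "")
  }
  expect_identical(map_read(mutate(read, c(40, 80, 120)), idx, params)$nm, 3L)
  expect_null(map_read(mutate(read, c(20, 40, 80, 120)), idx, params))
})

test_that("ambiguous reads from repeated sequence are dropped", {
  rep_unit <- "ACGTTGCAAGCTTGACGATCGTACGTGGCATCA"  # 33 nt
  seqn <- paste0("ATG", strrep(rep_unit, 4), "CATTGCCAGTCAGGCTAACGGATT", "TAA")
  p <- plasmid_map("reps", seqn, cds_start = 0L, cds_aa_length = 1L)
  idx <- index_reference(p, k = 11L)
  # a read wholly inside the repeat matches four places
  expect_null(map_read(substr(rep_unit, 1, 20), idx,
                       alignment_params(k = 11L)))
})

test_that("pairs reconstruct exact fragment intervals, circularly", {
  p <- toy_plasmid(orf_aa = 400L, total_len = 3000L, cds_start = 1000L)
  idx <- index_reference(p)
  params <- alignment_params(min_insert = 150L, max_insert = 600L)
  # includes origin-spanning fragments
  frags <- lib_df(c(1000L, 2900L, 2500L, 40L), c(350L, 300L, 550L, 200L),
                  c("+", "-", "+", "-"))
  rp <- simulate_read_pairs(frags, p, read_len = 150)
  res <- map_read_pairs(rp, idx, params)
  expect_true(all(res$fragments$status == "proper_pair"))
  expect_identical(res$fragments$start, frags$start)
  expect_identical(res$fragments$end - res$fragments$start, frags$length)
  expect_identical(res$fragments$strand, frags$strand)
})

test_that("same-strand and out-of-bounds pairs become singletons", {
  p <- toy_plasmid(orf_aa = 400L, total_len = 3000L, cds_start = 1000L)
  params <- alignment_params(min_insert = 100L, max_insert = 500L)
  m1 <- list(pos = 100L, strand = "+", nm = 0L, len = 150L)
  m2_same <- list(pos = 300L, strand = "+", nm = 0L, len = 150L)
  out <- fragmap:::pair_to_fragment("q", m1, m2_same, params, 3000L)
  expect_identical(out$status, c("singleton", "singleton"))
  m2_far <- list(pos = 1500L, strand = "-", nm = 0L, len = 150L)
  out2 <- fragmap:::pair_to_fragment("q", m1, m2_far, params, 3000L)
  expect_identical(out2$status, c("singleton", "singleton"))
  expect_identical(
    fragmap:::pair_to_fragment("q", NULL, NULL, params, 3000L)$status,
    "unmapped")
})

test_that("mapping is invariant under rotation of the circular reference", {
  p <- toy_plasmid(orf_aa = 300L, total_len = 2400L, cds_start = 800L)
  r <- 977L
  rotated <- paste0(substr(p$sequence, r + 1L, p$length),
                    substr(p$sequence, 1L, r))
  p2 <- plasmid_map("rot", rotated, cds_start = (p$cds_start - r) %% p$length,
                    cds_aa_length = p$cds_aa_length)
  idx1 <- index_reference(p); idx2 <- index_reference(p2)
  set.seed(31)
  for (rep in 1:10) {
    pos <- sample(0:(p$length - 1L), 1)
    read <- plasmid_subseq(p, pos, 120L)
    m1 <- map_read(read, idx1)
    m2 <- map_read(read, idx2)
    expect_identical(m2$pos, (m1$pos - r) %% p$length)
  }
})

test_that("dedup keeps one representative per (start, end, strand) and is idempotent", {
  f <- frag_df(c(10L, 10L, 10L, 10L, 50L), c(200L, 200L, 200L, 201L, 300L),
               c("+", "+", "-", "+", "+"))
  d1 <- dedup_fragments(f)
  expect_identical(sum(d1$duplicate), 1L)  # only the second (10,200,+) row
  expect_identical(nrow(unique_pe(d1)), 4L)
  expect_identical(dedup_fragments(d1), d1)
  # singletons are never in the UniquePE set
  f2 <- frag_df(10L, 200L, status = "singleton")
  expect_identical(nrow(unique_pe(dedup_fragments(f2))), 0L)
  # brute-force count on a random skewed library
  set.seed(17)
  s <- sample(1:40, 500, TRUE); e <- s + sample(100:110, 500, TRUE)
  st <- sample(c("+", "-"), 500, TRUE)
  d <- dedup_fragments(frag_df(s, e, st))
  expect_identical(nrow(unique_pe(d)),
                   nrow(unique(data.frame(s, e, st))))
})

test_that("SAM export/import round-trips the mapping result", {
  p <- toy_plasmid(orf_aa = 400L, total_len = 3000L, cds_start = 1000L)
  idx <- index_reference(p)
  params <- alignment_params(min_insert = 150L, max_insert = 600L)
  frags <- lib_df(c(100L, 700L, 1500L), c(350L, 300L, 400L), c("+", "-", "+"))
  rp <- simulate_read_pairs(frags, p, read_len = 150)
  rp$r1_seq[3] <- paste0(strrep("ACGT", 37), "AC")  # unmappable -> singleton
  res <- map_read_pairs(rp, idx, params)
  sam <- tempfile(fileext = ".sam")
  export_sam(res, sam)
  back <- import_sam(sam, p, params)
  expect_identical(back$fragments[, c("qname", "start", "end", "strand", "status")],
                   res$fragments[, c("qname", "start", "end", "strand", "status")])
  # header/reference mismatch is an error
  other <- toy_plasmid(orf_aa = 100L, total_len = 901L, cds_start = 300L,
                       name = "other", seed = 3L)
  expect_error(import_sam(sam, other), "does not match")
})

test_that("externally produced SAM (bwa mem) yields the same fragment intervals", {
  expect_true(nzchar(Sys.which("bwa")))
  p <- toy_plasmid(orf_aa = 600L, total_len = 3000L, cds_start = 500L,
                   name = "bwaref")
  set.seed(19)
  # keep fragments away from the origin: bwa sees a linear reference
  starts <- sample(100:2300, 80, TRUE)
  frags <- lib_df(starts, sample(300:400, 80, TRUE),
                  sample(c("+", "-"), 80, TRUE))
  rp <- simulate_read_pairs(frags, p, read_len = 150)
  dir <- tempfile(); dir.create(dir)
  fa <- file.path(dir, "ref.fa")
  write_plasmid(p, fa)
  write_fastq(rp, file.path(dir, "r1.fq"), file.path(dir, "r2.fq"))
  system2("bwa", c("index", fa), stdout = FALSE, stderr = FALSE)
  system2("bwa", c("mem", fa, file.path(dir, "r1.fq"), file.path(dir, "r2.fq")),
          stdout = file.path(dir, "aln.sam"), stderr = FALSE)
  params <- alignment_params(min_insert = 150L, max_insert = 600L)
  ext <- import_sam(file.path(dir, "aln.sam"), p, params)
  internal <- map_read_pairs(rp, index_reference(p), params)
  ef <- ext$fragments[ext$fragments$status == "proper_pair", ]
  inf <- internal$fragments[internal$fragments$status == "proper_pair", ]
  shared <- intersect(ef$qname, inf$qname)
  expect_gte(length(shared), 75L)
  a <- ef[match(shared, ef$qname), c("start", "end", "strand")]
  b <- inf[match(shared, inf$qname), c("start", "end", "strand")]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})
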