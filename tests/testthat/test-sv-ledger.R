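sv_call <- function(chrom, start, stop, svtype = "deletion", repeat_class = NA) {
  tibble::tibble(chrom = as.character(chrom), start = as.integer(start),
                 stop = as.integer(stop), svtype = svtype,
                 repeat_class = as.character(repeat_class))
}

test_that("candidate merging clusters by reciprocal overlap and is idempotent", {
  # identical deletions from two methods collapse to one candidate
  m <- merge_candidates(list(a = sv_call("1", 100, 200),
                             b = sv_call("1", 100, 200)))
  expect_equal(nrow(m), 1)
  expect_equal(m$supporting_methods, "a,b")
  expect_equal(m$state, "predicted")

  # disjoint calls stay apart; so do same-coordinate calls of different type
  m2 <- merge_candidates(list(a = sv_call("1", 100, 200),
                              b = sv_call("1", 500, 600)))
  expect_equal(nrow(m2), 2)
  m3 <- merge_candidates(list(a = sv_call("1", 100, 200, "deletion"),
                              b = sv_call("1", 100, 200, "insertion")))
  expect_equal(nrow(m3), 2)

  # 10 planted clusters across 4 synthetic methods
  set.seed(21)
  anchors <- seq(1000, by = 5000, length.out = 10)
  methods <- lapply(1:4, function(i) {
    jitter <- sample(-20:20, 10, replace = TRUE)
    dplyr::bind_rows(lapply(seq_along(anchors), function(j)
      sv_call("3", anchors[j] + jitter[j], anchors[j] + 400 + jitter[j])))
  })
  names(methods) <- paste0("m", 1:4)
  merged <- merge_candidates(methods)
  expect_equal(nrow(merged), 10)
  expect_true(all(merged$n_methods == 4))

  # idempotence: re-merging a merged set changes nothing
  again <- merge_candidates(list(merged = merged[c("chrom", "start", "stop",
                                                   "svtype", "repeat_class")]))
  expect_equal(again[c("chrom", "start", "stop", "svtype")],
               merged[c("chrom", "start", "stop", "svtype")])

  expect_error(merge_candidates(list(a = sv_call("1", 1, 2)),
                                reciprocal_overlap = 0), "reciprocal_overlap")
})

test_that("triage verdicts respect the state machine and reproduce the cascade", {
  ledger <- tibble::tibble(id = sprintf("c%03d", 1:551), state = "predicted")
  v1 <- stats::setNames(c(rep("false_pe_error", 470), rep("retained", 81)),
                        ledger$id)
  s1 <- apply_triage_verdicts(ledger, v1)
  expect_equal(unname(s1$counts["retained"]), 81)

  retained <- s1$ledger$id[s1$ledger$state == "retained"]
  v2 <- stats::setNames(c(rep("reference_error", 38), rep("validated", 43)),
                        retained)
  s2 <- apply_triage_verdicts(s1$ledger, v2)
  expect_equal(unname(s2$counts["validated"]), 43)
  expect_equal(unname(s2$counts["reference_error"]), 38)

  # validated is unreachable without passing retained
  expect_error(
    apply_triage_verdicts(ledger, c(c001 = "validated")), "illegal state")
  expect_error(
    apply_triage_verdicts(s2$ledger, stats::setNames("retained", retained[1])),
    "illegal state")
  expect_error(apply_triage_verdicts(ledger, c(zzz = "retained")), "unknown candidate")
})

test_that("gene overlap labels follow containment > exon > intron severity", {
  genes <- list(
    gene_model("Cyp2a22", "7", "+", data.frame(start = c(27700000, 27705000),
                                               end = c(27701000, 27706000))),
    gene_model("Tlk1", "2", "-", data.frame(start = c(70610000, 70630000),
                                            end = c(70612000, 70632000))),
    gene_model("Vmn2r65", "7", "+", data.frame(start = c(92095000, 92096100),
                                               end = c(92095500, 92096500)))
  )
  svs <- tibble::tibble(
    chrom = c("7", "2", "7", "5"),
    start = c(27636128L, 70619835L, 92095990L, 1L),
    stop = c(27748456L, 70620080L, 92096149L, 100L))
  ann <- annotate_gene_overlap(svs, genes)
  expect_equal(ann$overlap, c("entire", "intron", "exon", "none"))
  expect_equal(ann$gene, c("Cyp2a22", "Tlk1", "Vmn2r65", NA))

  # invariant to strand and to exon row order
  genes_flipped <- lapply(genes, function(g)
    gene_model(g$gene, g$chrom, if (g$strand == "+") "-" else "+",
               g$exons[rev(seq_len(nrow(g$exons))), ]))
  ann2 <- annotate_gene_overlap(svs, genes_flipped)
  expect_equal(ann2$overlap, ann$overlap)

  # multi-gene hit keeps the most severe label
  small <- gene_model("inner", "9", "+", data.frame(start = 150, end = 160))
  big <- gene_model("outer", "9", "+", data.frame(start = c(100, 400),
                                                  end = c(120, 500)))
  hit <- annotate_gene_overlap(tibble::tibble(chrom = "9", start = 130L,
                                              stop = 200L),
                               list(big, small))
  expect_equal(hit$overlap, "entire")
  expect_equal(hit$gene, "inner")
})

test_that("ancestral events are classified against the outgroup", {
  # LINE-matching gain absent in the rat: retrotransposition insertion
  ev <- classify_ancestral_event("insertion", "B6J",
                                 c(B6J = FALSE, B6N = TRUE), "LINE")
  expect_equal(ev$label, "LINE Ins")
  expect_equal(ev$rollup, "insertion")

  # plain gain with no repeat class
  expect_equal(classify_ancestral_event("insertion", "B6N",
                                        c(B6J = TRUE, B6N = FALSE))$label, "Ins")

  # derived loss: the deletion was called in B6N and the rat carries the
  # longer (B6J) allele, so B6N lost the sequence
  ev2 <- classify_ancestral_event("deletion", "B6N",
                                  c(B6J = TRUE, B6N = FALSE))
  expect_equal(ev2$label, "Del")
  expect_equal(ev2$rollup, "non_repeat")

  # a gain carried by the strain whose allele is ancestral is a loss elsewhere
  expect_equal(classify_ancestral_event("insertion", "B6J",
                                        c(B6J = TRUE, B6N = FALSE))$label, "Del")

  expect_equal(classify_ancestral_event("tandem_repeat", NA,
                                        c(B6J = TRUE, B6N = TRUE))$label, "VNTR")

  expect_error(classify_ancestral_event("insertion", "B6J",
                                        c(B6J = TRUE, B6N = TRUE)), "ambiguous")
  expect_error(classify_ancestral_event("deletion", "B6J",
                                        c(B6J = FALSE, B6N = FALSE)), "ancestral")
})

test_that("ledger summary reproduces every printed tally on the packaged table", {
  s <- summarize_svs(load_sv_table())
  expect_equal(s$n, 43)
  expect_equal(s$by_overlap,
               c(intron = 12L, exon = 2L, entire = 1L, none = 28L))
  expect_equal(s$by_rollup, c(insertion = 27L, non_repeat = 15L, vntr = 1L))
  expect_equal(unname(s$by_strain["unassigned"]), 1L)  # the VNTR row

  empty <- summarize_svs(tibble::tibble(overlap = character(),
                                        ancestral_event = character()))
  expect_equal(empty$n, 0)
  expect_true(all(empty$by_overlap == 0))
  expect_true(all(empty$by_rollup == 0))
})
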