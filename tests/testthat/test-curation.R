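# Confidence classification and full-name rendering.

hit_tomato <- function(e = 1e-25, id = 40, len = 120)
  homology_hit("XXX", "Solanum_lycopersicum", e_value = e,
               percent_identity = id, aligned_length = len)

test_that("the evidence ladder assigns the documented levels", {
  expect_equal(classify_confidence(evidence_bundle())$level, "hypothetical")

  expect_equal(
    classify_confidence(evidence_bundle(transcript_evidence = TRUE))$level,
    "expressed")

  lab <- classify_confidence(evidence_bundle(
    transcript_evidence = TRUE, homology_hits = hit_tomato()))
  expect_equal(lab$level, "similar_to")
  expect_equal(lab$payload, "XXX")

  dom <- classify_confidence(evidence_bundle(
    transcript_evidence = TRUE, domain_hits = "kinase",
    homology_hits = hit_tomato(e = 1e-5, id = 20, len = 50)))
  expect_equal(dom$level, "domain_containing")
  expect_equal(dom$payload, "kinase")

  named <- classify_confidence(evidence_bundle(
    transcript_evidence = TRUE,
    homology_hits = homology_hit("ADH1", "Vitis_vinifera", is_vitis = TRUE,
                                 is_characterized = TRUE, e_value = 1e-80,
                                 whole_sequence_identity = 96)))
  expect_equal(named$level, "named")
  expect_equal(named$payload, "ADH1")

  expect_equal(classify_confidence(evidence_bundle(
    transcript_evidence = TRUE, pseudogene_evidence = TRUE))$level,
    "uncertain")

  # below both similarity criteria the gene stays merely expressed
  expect_equal(classify_confidence(evidence_bundle(
    transcript_evidence = TRUE,
    homology_hits = hit_tomato(e = 1e-19, id = 25, len = 60)))$level,
    "expressed")
})

test_that("protein-level evidence stacks as the translated qualifier", {
  lab <- classify_confidence(evidence_bundle(
    transcript_evidence = TRUE, protein_evidence = TRUE,
    homology_hits = hit_tomato()))
  expect_equal(lab$level, "similar_to")
  expect_equal(lab$qualifiers, "translated")
  expect_equal(classify_confidence(evidence_bundle(
    protein_evidence = TRUE))$qualifiers, "translated")
})

test_that("functional evidence grades putative/probable/named", {
  expect_equal(classify_confidence(evidence_bundle(
    transcript_evidence = TRUE,
    functional_evidence = "in_silico"))$level, "putative")
  expect_equal(classify_confidence(evidence_bundle(
    transcript_evidence = TRUE,
    functional_evidence = "some_experimental"))$level, "probable")
  lab <- classify_confidence(evidence_bundle(
    functional_evidence = "characterized_in_vitis",
    functional_name = "TPS1"))
  expect_equal(lab$level, "named")
  expect_equal(lab$payload, "TPS1")
  expect_error(evidence_bundle(functional_evidence = "characterized_in_vitis"))
})

test_that("a GO code is recorded only with at least some experimental evidence", {
  expect_null(classify_confidence(evidence_bundle(
    transcript_evidence = TRUE, functional_evidence = "in_silico",
    go_code = "IEA"))$go_code)
  expect_equal(classify_confidence(evidence_bundle(
    functional_evidence = "some_experimental", go_code = "IDA"))$go_code,
    "IDA")
})

test_that("the best hit decides, with deterministic tie-breaking", {
  hits <- rbind(hit_tomato(e = 1e-25, id = 40, len = 120),
                homology_hit("YYY", "Populus", e_value = 1e-30,
                             percent_identity = 35, aligned_length = 100))
  lab <- classify_confidence(evidence_bundle(transcript_evidence = TRUE,
                                             homology_hits = hits))
  expect_equal(lab$payload, "YYY")
  # equal e-values: higher identity wins
  tie <- rbind(homology_hit("A", e_value = 1e-25, percent_identity = 50,
                            aligned_length = 90),
               homology_hit("B", e_value = 1e-25, percent_identity = 60,
                            aligned_length = 90))
  expect_equal(classify_confidence(evidence_bundle(
    transcript_evidence = TRUE, homology_hits = tie))$payload, "B")
})

test_that("thresholds sit exactly at the documented boundaries", {
  at <- function(e, id, len) classify_confidence(evidence_bundle(
    transcript_evidence = TRUE,
    homology_hits = homology_hit("X", e_value = e, percent_identity = id,
                                 aligned_length = len)))$level
  expect_equal(at(1e-20, 10, 10), "similar_to")      # e-value inclusive
  expect_equal(at(1.1e-20, 10, 10), "expressed")
  expect_equal(at(1e-5, 30, 80), "similar_to")       # identity/length inclusive
  expect_equal(at(1e-5, 29.9, 80), "expressed")
  expect_equal(at(1e-5, 30, 79), "expressed")

  transfer_at <- function(wsi) classify_confidence(evidence_bundle(
    homology_hits = homology_hit("ADH1", is_vitis = TRUE,
                                 is_characterized = TRUE, e_value = 1e-50,
                                 whole_sequence_identity = wsi)))$level
  expect_equal(transfer_at(95), "hypothetical")      # > 95 is exclusive
  expect_equal(transfer_at(95.1), "named")
})

test_that("boundary scanning recovers arbitrary configured thresholds", {
  tpl_e <- evidence_bundle(transcript_evidence = TRUE,
                           homology_hits = homology_hit(
                             "X", e_value = 1, percent_identity = 20,
                             aligned_length = 60))
  tpl_id <- evidence_bundle(transcript_evidence = TRUE,
                            homology_hits = homology_hit(
                              "X", e_value = 1e-5, percent_identity = 0,
                              aligned_length = 100))
  tpl_tr <- evidence_bundle(homology_hits = homology_hit(
    "Y", is_vitis = TRUE, is_characterized = TRUE, e_value = 1e-50,
    whole_sequence_identity = 0))
  for (th in list(confidence_thresholds(),
                  confidence_thresholds(evalue_cutoff = 1e-15,
                                        min_identity = 40,
                                        min_contiguous_length = 60,
                                        transfer_identity = 90))) {
    expect_equal(scan_threshold_boundary("e_value", tpl_e, 10^(-30:-10), th),
                 th$evalue_cutoff)
    expect_equal(scan_threshold_boundary("identity", tpl_id, 10:60, th),
                 th$min_identity)
    expect_equal(scan_threshold_boundary("transfer_identity", tpl_tr,
                                         80:100, th),
                 th$transfer_identity)
  }
})

test_that("improving one evidence axis never lowers the level", {
  for (seed in 1:60) {
    ev <- rand_bundle(seed)
    base <- level_rank(classify_confidence(ev)$level)
    improve <- list(
      function(e) { if (!is.null(e$homology_hits))
        e$homology_hits$e_value <- e$homology_hits$e_value / 1e6; e },
      function(e) { if (!is.null(e$homology_hits))
        e$homology_hits$percent_identity <-
          pmin(100, e$homology_hits$percent_identity + 30); e },
      function(e) { if (!is.null(e$homology_hits))
        e$homology_hits$aligned_length <-
          e$homology_hits$aligned_length + 100L; e },
      function(e) { e$transcript_evidence <- TRUE; e },
      function(e) { e$protein_evidence <- TRUE; e })
    for (f in improve) {
      upgraded <- level_rank(classify_confidence(f(ev))$level)
      expect_gte(upgraded, base)
    }
    # determinism: identical bundles, identical labels
    expect_identical(classify_confidence(ev), classify_confidence(ev))
  }
})

test_that("full names render per level and demand their payloads", {
  sim <- classify_confidence(evidence_bundle(
    transcript_evidence = TRUE,
    homology_hits = homology_hit("alcohol dehydrogenase", e_value = 1e-30)))
  expect_equal(render_full_name(sim), "similar to alcohol dehydrogenase")
  expect_equal(render_full_name(classify_confidence(evidence_bundle())),
               "hypothetical protein")
  put <- classify_confidence(evidence_bundle(
    transcript_evidence = TRUE, functional_evidence = "in_silico"))
  expect_equal(render_full_name(put, base_name = "sugar transporter"),
               "putative sugar transporter")
  expect_error(render_full_name(put))
  dom <- classify_confidence(evidence_bundle(
    transcript_evidence = TRUE, domain_hits = "kinase"))
  expect_equal(render_full_name(dom), "kinase domain containing protein")
})

test_that("the evidence-table reader classifies a small cohort", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(
    gene = c("g1", "g2", "g2", "g3"),
    transcript_evidence = c(TRUE, TRUE, TRUE, FALSE),
    protein_evidence = FALSE, pseudogene_evidence = c(FALSE, FALSE, FALSE, TRUE),
    functional_evidence = "none", functional_name = "",
    domains = "",
    subject_name = c("", "HOMA", "HOMB", ""),
    subject_species = "", is_vitis = FALSE, is_characterized = FALSE,
    e_value = c(NA, 1e-30, 1e-3, NA),
    percent_identity = c(NA, 45, 10, NA),
    aligned_length = c(NA, 150, 30, NA),
    whole_sequence_identity = c(NA, 40, 8, NA),
    stringsAsFactors = FALSE)
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  res <- classify_evidence_table(tsv)
  expect_equal(res$level[res$gene == "g1"], "expressed")
  expect_equal(res$level[res$gene == "g2"], "similar_to")
  expect_equal(res$payload[res$gene == "g2"], "HOMA")
  expect_equal(res$level[res$gene == "g3"], "uncertain")
})
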