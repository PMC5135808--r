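# Shared fixtures, built once per test session. Seeds are fixed so every
# run sees identical data.

tiny_bundle <- suppressMessages(make_fixture_bundle("tiny", seed = 42))

# recurrence scores and labeled set for the tiny bundle
tiny_records <- score_cohort(tiny_bundle$cohort, w = 10, B = 1e4)
tiny_labeled <- suppressWarnings(
  build_labeled_set(tiny_records, "significance", 5e-6, seed = 1)
)

# hotspot membership per scored record
tiny_hotspot_id <- function(records = tiny_records) {
  key <- paste(records$chrom, records$pos, records$ref, records$alt,
    records$sample_id,
    sep = ":"
  )
  tiny_bundle$truth$hotspot_id[match(key, tiny_bundle$truth$key)]
}
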