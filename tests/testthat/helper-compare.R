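# The end-to-end comparison runs are the most expensive fixtures in the
# suite; build each phantom's run once and share it across test blocks.
.compareCache <- new.env(parent = emptyenv())

cachedCompare <- function(preset, prfHz = c(100, 500, 1000), seed = 7L) {
  key <- paste(preset, paste(prfHz, collapse = "_"), seed, sep = "|")
  if (is.null(.compareCache[[key]]))
    .compareCache[[key]] <- comparePlans(preset, prfHz = prfHz, seed = seed)
  .compareCache[[key]]
}
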