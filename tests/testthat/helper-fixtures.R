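# In-code fixtures; all chemistry uses vocabulary SMILES that are already
# canonical, so fixture construction never needs the RDKit round trip.

make_ds <- function(id, smiles, logS, weight = 1.0,
                    quality_weight = 1.0, group = "high", ...) {
  rec <- data.frame(smiles = smiles, logS = logS, weight = weight,
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) rec[[nm]] <- extra[[nm]]
  solubility_dataset(id, rec, quality_weight = quality_weight, group = group)
}

# the seven reference sources as empty datasets carrying weights/groups,
# for schedule tests
reference_sources <- function() {
  tab <- solubility_sources()
  lapply(seq_len(nrow(tab)), function(i) {
    make_ds(tab$id[i], smiles = "CCO", logS = -0.24,
            quality_weight = if (is.na(tab$quality_weight[i])) NULL else
              tab$quality_weight[i],
            group = tab$group[i])
  })
}
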