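#!/usr/bin/env Rscript
# Stub: genome-database coverage census.
#
# Computing metabolite/reaction decomposition coverage over the KEGG database
# requires a local KEGG dump (compound InChI strings and reaction equations),
# which this package never downloads. Given such a dump as two TSVs --
# compounds.tsv (compound_id, inchi) and reactions.tsv (reaction) -- this
# script decomposes every metabolite, builds the moiety incidence matrix from
# a training compound set, and reports what fraction of reactions is covered
# by the trained moiety alphabet (coverage_percent over parseable entries).
#
# usage: Rscript scripts/kegg_coverage_stub.R <kegg_compounds.tsv> <kegg_reactions.tsv> <model.json>

suppressMessages(library(moietherm))
args <- commandArgs(trailingOnly = TRUE)
if (length(args) != 3) {
  stop("usage: kegg_coverage_stub.R <kegg_compounds.tsv> <kegg_reactions.tsv> <model.json>\n",
       "A local database dump is required; nothing is downloaded.")
}
compounds <- load_compound_table(args[1])
tab <- utils::read.delim(args[2], stringsAsFactors = FALSE)
model <- read_model(args[3])
G <- build_incidence(compounds, radii = model$radii, stereo = model$stereo)
covered <- vapply(tab$reaction, function(txt) {
  ok <- tryCatch({
    x <- moiety_change(parse_reaction(txt), G)
    all(names(x[x != 0]) %in% model$moiety_index)
  }, error = function(e) NA)
  ok
}, logical(1))
cat(sprintf("metabolites decomposed: %d/%d (%.1f%%)\n",
            nrow(G), nrow(compounds), coverage_percent(nrow(G), nrow(compounds))))
cat(sprintf("reactions covered by trained moieties: %.1f%% (of %d evaluable)\n",
            coverage_percent(sum(covered, na.rm = TRUE), sum(!is.na(covered))),
            sum(!is.na(covered))))
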