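# shared fixtures, built in code

SPIKE_LINEAGE <-
  "Archaea;Crenarchaeota;Thermoprotei;Sulfolobales;Sulfolobaceae;Saccharolobus"

# a small SSU profile with a spike clade, an Enterobacteriaceae vector trace
# and a mixed community
fixtureProfile <- function(sample_id = "s1", protocol = "unknown") {
  TaxonProfile(
    c(400, 250, 150, 120, 50, 21, 9),
    lineages = c(
      "Bacteria;Actinomycetota;Actinomycetes;Micrococcales;Micrococcaceae;Arthrobacter",
      "Bacteria;Pseudomonadota;Alphaproteobacteria;Rhizobiales;Rhizobiaceae;Rhizobium",
      "Eukaryota;Cercozoa;Sarcomonadea;Glissomonadida;Allapsidae;Allapsa",
      "Bacteria;Acidobacteriota;Acidobacteriae;Bryobacterales;Bryobacteraceae;Paludibaculum",
      "Archaea;Thermoproteota;Nitrososphaeria;Nitrososphaerales;Nitrososphaeraceae;Nitrososphaera",
      SPIKE_LINEAGE,
      "Bacteria;Pseudomonadota;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Escherichia-Shigella"
    ),
    sample_id = sample_id, protocol = protocol)
}

# random profile over n shared taxon names, for fuzz/oracle tests
randomProfile <- function(n_taxa = 20, sample_id = "r", max_count = 50) {
  lin <- sprintf("Bacteria;Phy%d;Cls%d;Ord%d;Fam%d;Gen%d",
                 seq_len(n_taxa) %% 5, seq_len(n_taxa) %% 7,
                 seq_len(n_taxa), (seq_len(n_taxa) - 1) %/% 2 + 1,
                 seq_len(n_taxa))
  cnt <- sample.int(max_count, n_taxa, replace = TRUE) *
    rbinom(n_taxa, 1, 0.8)
  if (sum(cnt) == 0) cnt[1] <- 1
  TaxonProfile(cnt, lineages = lin, sample_id = sample_id)
}

# definition-level two-loop Bray-Curtis oracle on counts
bruteForceBrayCurtis <- function(a, b) {
  ra <- taxonCounts(a) / totalReads(a)
  rb <- taxonCounts(b) / totalReads(b)
  taxa <- union(names(ra), names(rb))
  num <- 0; den <- 0
  for (t in taxa) {
    x <- if (t %in% names(ra)) ra[[t]] else 0
    y <- if (t %in% names(rb)) rb[[t]] else 0
    num <- num + abs(x - y)
    den <- den + (x + y)
  }
  num / den
}

# tiny labelled pools for mock experiments
mockPools <- function(comm_entero_frac = 0.001, comm_total = 1e6,
                      spike_total = 6e5) {
  comm <- c(
    "Bacteria;Bacillota;Bacilli;Bacillales;Bacillaceae;Bacillus" =
      round(comm_total * 0.4),
    "Eukaryota;Cercozoa;Sarcomonadea;Glissomonadida;Allapsidae;Allapsa" =
      round(comm_total * 0.3),
    "Bacteria;Pseudomonadota;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Escherichia-Shigella" =
      round(comm_total * comm_entero_frac),
    "Bacteria;Acidobacteriota;Acidobacteriae;Bryobacterales;Bryobacteraceae;Paludibaculum" =
      round(comm_total * (0.3 - comm_entero_frac)))
  spike <- c(
    structure(round(spike_total * 0.999), names = SPIKE_LINEAGE),
    "Bacteria;Pseudomonadota;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Escherichia-Shigella" =
      round(spike_total * 0.001))
  list(community = comm, spike = spike)
}
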