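# Fixtures are built in code: a toy 2x2 survey, writers for temp files, and
# random generators used by the property-style tests.

toy_records <- function() {
  data.frame(
    sample_id = c("s1", "s1", "s2"),
    stratum = c("DHK", "DHK", "DHK"),
    season = c("Mar", "Mar", "Jun"),
    species_id = c("spA", "spB", "spA"),
    n = c(50, 10, 8),
    v = c(2.5, 2.5, 2),
    stringsAsFactors = FALSE)
}

write_toy_community <- function(records = toy_records(), sep = ",") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  write.table(records, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

toy_traits <- function() {
  data.frame(
    species_id = c("spA", "spB"),
    taxon_class = c("rotifer", "copepod_cladoceran"),
    body_size_mm = c(NA, 2.0),
    feeding_habit = c("filter", "filter"),
    stringsAsFactors = FALSE)
}

write_toy_traits <- function(df = toy_traits()) {
  path <- tempfile(fileext = ".csv")
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
              na = "")
  path
}

# random proportional-use profile over r states
random_profile <- function(r) {
  x <- stats::rexp(r)
  x / sum(x)
}

# random binary presence matrix guaranteed free of constant rows
random_presence <- function(n_entities, n_sites) {
  repeat {
    m <- matrix(stats::rbinom(n_entities * n_sites, 1, 0.5),
                nrow = n_entities,
                dimnames = list(paste0("e", seq_len(n_entities)), NULL))
    rs <- rowSums(m)
    if (all(rs > 0 & rs < n_sites)) return(m)
  }
}

# small synthetic scenario used where the full preset would be overkill
small_scenario <- function(seed = 7, ...) {
  scenario_config(
    strata = c("A", "B"), seasons = c("Mar", "Jun"),
    stations_per_stratum = 2,
    species_plan = c(rotifer = 4, copepod = 6, protozoan = 4, other = 3,
                     cladoceran = 2),
    seed = seed, ...)
}
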