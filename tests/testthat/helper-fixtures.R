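# Shared fixtures built in code.

table1 <- function() default_anchor_table()

# Independent simple-regression oracle: closed-form normal equations for
# albedo on sqrt(day), bypassing fit_sqrt_decay's internals.
ols_sqrt_oracle <- function(day, albedo) {
  x <- sqrt(day)
  slope <- sum((x - mean(x)) * (albedo - mean(albedo))) / sum((x - mean(x))^2)
  list(a = mean(albedo) - slope * mean(x), b = -slope)
}

toy_otu <- function() {
  counts <- rbind(S1 = c(5, 3, 0, 1, 10),
                  S2 = c(2, 0, 1, 0, 12),
                  S3 = c(4, 6, 0, 0, 8))
  colnames(counts) <- paste0("OTU", 1:5)
  otu_table(counts, c(
    "k__Bacteria; p__Bacteroidetes; c__Sphingobacteria",
    "k__Bacteria; p__Bacteroidetes; c__Sphingobacteria",
    "k__Bacteria; p__Bacteroidetes; c__Cytophagia",
    "k__Bacteria; p__Proteobacteria; c__Betaproteobacteria",
    "k__Bacteria"))
}

small_config <- function(...) {
  study_config(locations = c(SVA = 6L, TAR = 8L, MIT = 2L, ICE = 2L), ...)
}
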