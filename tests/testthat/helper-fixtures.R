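# Small in-code fixtures shared across test files.

# 2-condition x 2-replicate toy: 4 samples, 3 OTUs across 2 classes.
toy_table <- function() {
  m <- matrix(c(30L, 40L, 30L,
                28L, 42L, 30L,
                60L, 20L, 20L,
                58L, 22L, 20L),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("S", 1:4), paste0("OTU", 1:3)))
  m
}

toy_taxonomy <- function() {
  data.frame(otu_id = paste0("OTU", 1:3),
             lineage = c("Bacteria;Firmicutes;Bacilli",
                         "Bacteria;Proteobacteria;Gammaproteobacteria",
                         "Bacteria;Proteobacteria;Gammaproteobacteria"),
             class_label = c("Bacilli", "Gammaproteobacteria",
                             "Gammaproteobacteria"),
             stringsAsFactors = FALSE)
}

toy_metadata <- function() {
  data.frame(sample_id = paste0("S", 1:4),
             enzyme = c("EnzA", "EnzA", "EnzB", "EnzB"),
             temperature_c = c(42, 42, 55, 55),
             replicate = c("R1", "R2", "R1", "R2"),
             condition = c("EnzA 42", "EnzA 42", "EnzB 55", "EnzB 55"),
             stringsAsFactors = FALSE)
}

# metadata for an arbitrary samples x conditions layout
make_metadata <- function(sample_ids, conditions) {
  enz <- paste0("Enz", conditions)
  data.frame(sample_id = sample_ids, enzyme = enz, temperature_c = 50,
             replicate = make.unique(conditions),
             condition = paste(enz, 50), stringsAsFactors = FALSE)
}

# quick scenario for fast end-to-end tests
small_scenario <- function(..., seed = 42) {
  sim_scenario(n_classes = 20, otus_per_class = 2, depth = 2000,
               replicates = 4, seed = seed, ...)
}
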