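# Hand-built 18-sample toy: one site, species A (5 individuals) and
# species B (4 individuals), paired root/soil, every sample filled to
# exactly 1e6 reads so that 0.01% relative abundance is exactly 100 reads.
toy_table <- function() {
  inds <- c(paste0("a", 1:5), paste0("b", 1:4))
  species <- rep(c("A", "B"), c(5, 4))
  md <- rbind(
    data.frame(sample_id = paste0(inds, "_root"), site = "S1",
               plant_species = species, altitude = "low",
               sample_type = "root", individual = inds),
    data.frame(sample_id = paste0(inds, "_soil"), site = "S1",
               plant_species = species, altitude = "low",
               sample_type = "soil", individual = inds))
  otus <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "M", "L")
  X <- matrix(0, nrow = length(otus), ncol = nrow(md),
              dimnames = list(otus, md$sample_id))
  rt <- function(i) paste0(i, "_root")
  sl <- function(i) paste0(i, "_soil")
  X["A", rt(c("a1", "a2", "a3"))] <- 5000           # 3/5 of A, abundant
  X["A", sl("a1")] <- 500
  X["B", rt(c("a1", "a2"))] <- 150                  # 2/5 < 50% everywhere
  X["B", sl("a2")] <- 150
  X["C", rt(inds)] <- 1                             # ubiquitous but 1 read
  X["D", rt("a1")] <- 150                           # abundant once,
  X["D", rt(c("a2", "a3"))] <- 1                    # detected in 3/5 of A
  X["E", sl("b1")] <- 5000                          # soil only
  X["F", sl("a3")] <- 50                            # soil, below floor
  X["G", rt(inds)] <- 50                            # roots below floor
  X["G", sl("a4")] <- 300
  X["H", rt(c("b1", "b2", "b3"))] <- 150            # 3/4 of B
  X["I", rt("a1")] <- 100                           # exactly 0.01%: excluded
  X["I", rt(c("a2", "a3"))] <- 1                    # prevalence 3/5 passes
  X["I", sl("a5")] <- 100
  X["J", rt(c("b1", "b2"))] <- 150                  # exactly 50% of B
  X["L", ] <- 1e6 - colSums(X)                      # filler, dominant everywhere
  list(counts = X, metadata = md)
}
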