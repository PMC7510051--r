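# Shared fixtures, all built in code.

# Small deterministic count table.
tiny_counts <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    otuA = c(10, 0, 4),
    otuB = c(5, 8, 0),
    otuC = c(0, 2, 6))
}

# Ten-sample QC fixture forcing the whole chain:
#   s01 control; s02 low depth (400 reads); s03 Pezizomycotina mold OTU at
#   35% of reads; s04 Umbelopsidales mold OTU at exactly 15% (boundary,
#   retained); s05-s10 benign. otu_block is blocklisted.
qc_fixture <- function() {
  counts <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:10),
    otu_pez  = c(10,  10, 350, 50, 20, 10, 10, 10, 10, 10),
    otu_umb  = c(10,  10,  50, 150, 20, 10, 10, 10, 10, 10),
    otu_mort = c(10,  10,  50, 100, 20, 10, 10, 10, 10, 10),
    otu_reg1 = c(300, 200, 300, 400, 300, 400, 400, 400, 400, 400),
    otu_reg2 = c(300, 150, 250, 300, 300, 300, 300, 300, 300, 300),
    otu_block = c(20, 20, 0, 0, 40, 30, 20, 10, 5, 5))
  metadata <- tibble::tibble(
    sample_id = counts$sample_id,
    is_control = c(TRUE, rep(FALSE, 9)))
  assignments <- tibble::tibble(
    otu_id = setdiff(names(counts), "sample_id"),
    mold_group = c("Pezizomycotina_mold", "Umbelopsidales",
                   "Mortierellales", NA, NA, NA))
  list(counts = counts, metadata = metadata, assignments = assignments,
       thresholds = fungalscape::qc_thresholds(otu_blocklist = "otu_block"))
}

# Hit-table rows for one OTU with a shared taxonomy path.
make_hits <- function(otu_id, n = 10, similarity = 98, evalue = 1e-100,
                      kingdom = "Fungi", phylum = "Basidiomycota",
                      class = "Agaricomycetes", order = "Russulales",
                      family = "Russulaceae", genus = "Russula") {
  tibble::tibble(otu_id = otu_id, hit_order = seq_len(n),
                 similarity = rep_len(similarity, n),
                 evalue = rep_len(evalue, n),
                 kingdom = kingdom, phylum = phylum, class = class,
                 order = order, family = family, genus = genus)
}

# Noise-free hit table reproducing the synthetic truth taxonomy.
truth_hits <- function(taxonomy) {
  purrr::map_dfr(seq_len(nrow(taxonomy)), function(i) {
    make_hits(taxonomy$otu_id[i], n = 10, similarity = 99,
              evalue = 1e-120,
              kingdom = taxonomy$kingdom[i], phylum = taxonomy$phylum[i],
              class = taxonomy$class[i], order = taxonomy$order[i],
              family = taxonomy$family[i], genus = taxonomy$genus[i])
  })
}

# All permutations of 1..n (small n only).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Every binary matrix with the given row and column sums (brute force).
enumerate_margin_matrices <- function(rs, cs) {
  n <- length(rs) * length(cs)
  out <- list()
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n)]
    m <- matrix(bits, length(rs), length(cs))
    if (all(rowSums(m) == rs) && all(colSums(m) == cs)) {
      out[[length(out) + 1]] <- m
    }
  }
  out
}
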