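# Small in-code fixtures shared across test files.

# Locus table from parallel vectors, with sensible defaults.
make_loci <- function(gene_id, species_id, chromosome_id, start,
                      end = start + 100L, strand = "+") {
  data.frame(gene_id = gene_id, species_id = species_id,
             chromosome_id = chromosome_id, start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

# Orthology table: families is a named list family_id -> named character
# vector species -> gene. Species missing from a family become NA.
make_orthology <- function(families) {
  species <- sort(unique(unlist(lapply(families, names))))
  df <- data.frame(family_id = names(families), stringsAsFactors = FALSE)
  for (sp in species) {
    df[[sp]] <- vapply(families, function(f) {
      if (sp %in% names(f)) unname(f[[sp]]) else NA_character_
    }, "")
  }
  df
}

# A called profile with chosen significant ALG sets per chromosome.
# sig_sets: named list "species\rchromosome" is awkward; take a data frame.
make_called_profile <- function(species_id, chromosome_id, sig_algs) {
  rows <- lapply(seq_along(species_id), function(i) {
    algs <- sig_algs[[i]]
    if (length(algs) == 0L) {
      data.frame(species_id = species_id[i],
                 chromosome_id = chromosome_id[i],
                 alg = NA_character_, count = 0L, n_assigned = 0L,
                 p = NA_real_, q = NA_real_, significant = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(species_id = species_id[i],
                 chromosome_id = chromosome_id[i],
                 alg = algs, count = 20L, n_assigned = 20L * length(algs),
                 p = 1e-10, q = 1e-9, significant = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

# Direct-summation hypergeometric upper tail, independent of phyper.
hyper_tail_oracle <- function(count, alg_total, genome_total, chrom_size) {
  i <- count:min(alg_total, chrom_size)
  sum(exp(lchoose(alg_total, i) +
          lchoose(genome_total - alg_total, chrom_size - i) -
          lchoose(genome_total, chrom_size)))
}

# Brute-force conditional NB exact p: loop over splits, dnbinom products.
nb_exact_oracle <- function(ya, yb, na, nb, phi) {
  t <- ya + yb
  if (t == 0) return(1)
  probs <- numeric(t + 1)
  for (k in 0:t) {
    if (phi == 0) {
      probs[k + 1] <- dbinom(k, t, na / (na + nb))
    } else {
      probs[k + 1] <- dnbinom(k, size = na / phi, mu = na * 7.3) *
        dnbinom(t - k, size = nb / phi, mu = nb * 7.3)
    }
  }
  probs <- probs / sum(probs)
  sum(probs[probs <= probs[ya + 1] * (1 + 1e-10)])
}

# Pearson chi-square by hand for a 2x2 conservation table.
chi2_oracle <- function(kf, nf, kb, nb) {
  O <- matrix(c(kf, nf - kf, kb, nb - kb), 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

# Exact permutation p for the conservation chi-square via hypergeometric
# enumeration of all relabellings.
perm_p_oracle <- function(kf, nf, kb, nb) {
  k <- kf + kb
  n <- nf + nb
  obs <- chi2_oracle(kf, nf, kb, nb)
  ks <- max(0, k - nb):min(nf, k)
  w <- dhyper(ks, k, n - k, nf)
  st <- vapply(ks, function(x) chi2_oracle(x, nf, k - x, nb), 1.0)
  sum(w[st >= obs - 1e-12])
}
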