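#' Define a synthetic study scenario
#'
#' Collects every parameter of the synthetic-data generator in one
#' serialisable record, so a scenario is exactly reproducible from its
#' parameters and seed. The generator emulates the statistical structure the
#' pathway model assumes: LD-blocked biallelic genotypes in Hardy-Weinberg
#' proportions, genes tiling a chromosome with pathways drawing overlapping
#' gene sets, group-sparse causal SNP effects acting on a rank-1
#' multivariate phenotype, and longitudinal voxel values whose slopes differ
#' by diagnosis in a subset of voxels.
#'
#' @param n subjects.
#' @param n_genes genes tiling the simulated chromosome.
#' @param snps_per_gene SNPs per gene (P = n_genes * snps_per_gene).
#' @param l number of pathways.
#' @param genes_per_pathway integer range (min, max) of genes drawn per
#'   pathway.
#' @param overlap_rate probability that a pathway gene slot re-draws a gene
#'   already used by an earlier pathway.
#' @param n_causal_pathways number of causal pathways.
#' @param causal_fraction fraction of each causal pathway's SNPs given a
#'   non-zero effect.
#' @param effect_size standard deviation of the genetic latent factor
#'   `X b*` across subjects (causal SNPs share one magnitude, random sign).
#' @param noise_sd standard deviation of the phenotype error matrix.
#' @param q phenotype columns (voxels) for the rank-1 phenotype.
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param ld_block_size SNPs per LD block.
#' @param ld_rho latent within-block correlation, in [0, 1).
#' @param timepoints follow-up times in months for the longitudinal stage.
#' @param q_voxels voxels in the longitudinal stage.
#' @param n_discriminative voxels whose slope mean differs by diagnosis.
#' @param prop_ad proportion of AD subjects.
#' @param ad_slope_mean,cn_slope_mean per-month slope means (percent change
#'   per month) at discriminative voxels; defaults 0.1 (1.2 %/year) for AD
#'   and 0.02 for CN.
#' @param slope_sd between-subject SD of voxel slopes.
#' @param long_noise_sd measurement noise SD around the per-subject line.
#' @param age_range subject age range (years).
#' @param window_bp SNP-to-gene mapping window.
#' @param seed master seed; the genotype, pathway, phenotype and
#'   longitudinal generators use fixed offsets from it.
#' @return A list of class `psrrr_scenario`.
#' @export
psrrr_scenario <- function(n = 200, n_genes = 40, snps_per_gene = 5,
                           l = 10, genes_per_pathway = c(2, 6),
                           overlap_rate = 0.2, n_causal_pathways = 2,
                           causal_fraction = 0.5, effect_size = 0.7,
                           noise_sd = 0.5, q = 20,
                           maf_range = c(0.1, 0.5), ld_block_size = 5,
                           ld_rho = 0.5, timepoints = c(6, 12, 24),
                           q_voxels = 50, n_discriminative = 10,
                           prop_ad = 0.4, ad_slope_mean = 0.1,
                           cn_slope_mean = 0.02, slope_sd = 0.02,
                           long_noise_sd = 0.1, age_range = c(60, 90),
                           window_bp = 10000, seed = 1) {
  if (ld_rho < 0 || ld_rho >= 1) stop("`ld_rho` must lie in [0, 1).")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("`maf_range` must lie within (0, 0.5].")
  }
  if (n_causal_pathways > l) stop("More causal pathways than pathways.")
  scn <- as.list(environment())
  structure(scn, class = "psrrr_scenario")
}

# LD blocks nest within genes: genes are spaced tens of kilobases apart, so
# linkage does not extend across them. Returns a per-SNP block index.
ld_blocks <- function(scn) {
  k <- scn$snps_per_gene
  per_gene <- ceiling(seq_len(k) / scn$ld_block_size)
  blocks_per_gene <- max(per_gene)
  as.integer(rep((seq_len(scn$n_genes) - 1L) * blocks_per_gene, each = k) +
               rep(per_gene, scn$n_genes))
}

# gene g occupies [gene_start(g), gene_start(g) + span]; genes are spaced
# far enough apart that a 10 kb window cannot bleed into a neighbour
gene_layout <- function(scn) {
  spacing <- 2L * scn$window_bp + 10000L
  starts <- (seq_len(scn$n_genes) - 1L) * spacing + 1L
  span <- (scn$snps_per_gene + 1L) * 100L
  tibble::tibble(
    gene_id = sprintf("gene%03d", seq_len(scn$n_genes)),
    chromosome = "1",
    start_bp = starts,
    end_bp = starts + span
  )
}

#' Simulate LD-blocked biallelic genotypes
#'
#' Gaussian-copula generator: a latent standard normal with equicorrelation
#' `ld_rho` within consecutive blocks of `ld_block_size` SNPs is thresholded
#' at each SNP's Hardy-Weinberg genotype quantiles, giving counts in
#' \{0, 1, 2\} with the requested MAF and block-correlated genotypes. SNP
#' positions follow the gene tiling of the scenario so every SNP maps to
#' exactly one gene at the scenario window.
#'
#' @param scn a [psrrr_scenario()].
#' @return A [genotype_data()] object with P = `n_genes * snps_per_gene`
#'   SNPs.
#' @export
simulate_genotypes <- function(scn) {
  stopifnot(inherits(scn, "psrrr_scenario"))
  withr::with_seed(scn$seed + 1L, {
    p <- scn$n_genes * scn$snps_per_gene
    n <- scn$n
    maf <- runif(p, scn$maf_range[1], scn$maf_range[2])
    block_of <- ld_blocks(scn)
    n_blocks <- max(block_of)
    shared <- matrix(rnorm(n * n_blocks), n, n_blocks)
    z <- sqrt(scn$ld_rho) * shared[, block_of, drop = FALSE] +
      sqrt(1 - scn$ld_rho) * matrix(rnorm(n * p), n, p)
    q0 <- stats::qnorm((1 - maf)^2)
    q1 <- stats::qnorm((1 - maf)^2 + 2 * maf * (1 - maf))
    counts <- sweep(z, 2, q0, ">") + sweep(z, 2, q1, ">")
    genes <- gene_layout(scn)
    pos <- unlist(lapply(seq_len(scn$n_genes), function(g) {
      genes$start_bp[g] + seq_len(scn$snps_per_gene) * 100L
    }), use.names = FALSE)
    genotype_data(
      counts,
      sample_ids = sprintf("subj%04d", seq_len(n)),
      snp_ids = sprintf("snp%05d", seq_len(p)),
      chromosome = rep("1", p),
      position_bp = pos
    )
  })
}

#' Simulate a gene table, pathway database and mapping
#'
#' Genes tile the simulated chromosome (same layout as
#' [simulate_genotypes()]); each pathway draws between
#' `genes_per_pathway[1]` and `genes_per_pathway[2]` genes, re-using a gene
#' already claimed by an earlier pathway with probability `overlap_rate`.
#' The mapping itself is built through the real pipeline
#' ([map_snps_to_genes()] + [build_pathway_mapping()], without dropping the
#' largest pathway), so the generator exercises the same code the analysis
#' uses.
#'
#' @param scn a [psrrr_scenario()].
#' @param genotypes optionally, the [simulate_genotypes()] result (re-made
#'   from the scenario when missing).
#' @return List with `genes` (tibble), `pathway_db` (named list),
#'   `snp_gene_map`, and `mapping` (a `pathway_mapping`).
#' @export
simulate_pathways <- function(scn, genotypes = NULL) {
  stopifnot(inherits(scn, "psrrr_scenario"))
  if (is.null(genotypes)) genotypes <- simulate_genotypes(scn)
  genes <- gene_layout(scn)
  db <- withr::with_seed(scn$seed + 2L, {
    used <- character(0)
    unused <- genes$gene_id
    out <- list()
    for (l in seq_len(scn$l)) {
      k <- sample(seq(scn$genes_per_pathway[1], scn$genes_per_pathway[2]), 1)
      members <- character(0)
      for (slot in seq_len(k)) {
        pool_used <- setdiff(used, members)
        pool_new <- setdiff(unused, members)
        take_used <- length(pool_used) > 0 && scn$overlap_rate > 0 &&
          (length(pool_new) == 0 || runif(1) < scn$overlap_rate)
        if (!take_used && length(pool_new) == 0) {
          stop("Infeasible overlap/size combination: gene pool exhausted.")
        }
        pick <- if (take_used) sample(pool_used, 1) else sample(pool_new, 1)
        members <- c(members, pick)
      }
      used <- union(used, members)
      unused <- setdiff(unused, members)
      out[[sprintf("pathway%02d", l)]] <- members
    }
    out
  })
  sg <- map_snps_to_genes(genotypes, genes, window_bp = scn$window_bp)
  mapping <- suppressMessages(
    build_pathway_mapping(sg, db, drop_largest = FALSE)
  )
  list(genes = genes, pathway_db = db, snp_gene_map = sg, mapping = mapping)
}

#' Simulate a rank-1 multivariate phenotype with group-sparse SNP effects
#'
#' Draws `b*` supported on the causal pathways (a `causal_fraction` of each
#' causal pathway's distinct SNPs receives an equal-magnitude effect with
#' random sign), a unit-norm phenotype direction `a*`, and returns
#' `Y = X b* a*' + E` with i.i.d. Gaussian errors, together with the
#' ground-truth record. `b*` is scaled so the genetic latent factor `X b*`
#' has standard deviation `effect_size` across subjects: with `noise_sd = 1`
#' the default `effect_size = 0.7` makes genetics explain roughly a third of
#' the variance along `a*`, a strong-heritability endophenotype.
#'
#' @param scn a [psrrr_scenario()].
#' @param X standardised N x P design in genotype column order (original
#'   SNPs, not expanded).
#' @param mapping the scenario's `pathway_mapping` (from
#'   [simulate_pathways()]).
#' @return List with `Y` (N x q matrix) and `truth` (list: `b_star`,
#'   `a_star`, `causal_pathways`, `causal_snps` — SNP column indices).
#' @export
simulate_phenotype <- function(scn, X, mapping) {
  stopifnot(inherits(scn, "psrrr_scenario"))
  withr::with_seed(scn$seed + 3L, {
    p <- ncol(X)
    causal_pw <- sort(sample.int(length(mapping$pathways),
                                 scn$n_causal_pathways))
    b_star <- numeric(p)
    causal_snps <- integer(0)
    # one effect sign per LD block: correlated tag SNPs of a shared causal
    # haplotype act in a consistent direction
    block_of <- ld_blocks(scn)
    block_sign <- sample(c(-1, 1), max(block_of), replace = TRUE)
    for (l in causal_pw) {
      snps <- mapping$groups[[l]]
      k <- max(1L, round(scn$causal_fraction * length(snps)))
      chosen <- sort(sample(snps, k))
      b_star[chosen] <- block_sign[block_of[chosen]]
      causal_snps <- union(causal_snps, chosen)
    }
    if (scn$effect_size > 0) {
      u_sd <- stats::sd(as.numeric(X %*% b_star))
      if (u_sd > 0) b_star <- b_star * scn$effect_size / u_sd
    } else {
      b_star[] <- 0
    }
    a_star <- rnorm(scn$q)
    a_star <- a_star / sqrt(sum(a_star^2))
    if (a_star[which.max(abs(a_star))] < 0) a_star <- -a_star
    E <- matrix(rnorm(nrow(X) * scn$q, sd = scn$noise_sd), nrow(X), scn$q)
    Y <- (X %*% b_star) %*% t(a_star) + E
    list(
      Y = Y,
      truth = list(
        b_star = b_star, a_star = a_star,
        causal_pathways = mapping$pathways[causal_pw],
        causal_pathway_index = causal_pw,
        causal_snps = sort(causal_snps)
      )
    )
  })
}

#' Simulate longitudinal voxel values and subject covariates
#'
#' Per subject and voxel, values follow `intercept + slope * t + noise` at
#' the scenario timepoints. The first `n_discriminative` voxels draw their
#' slope mean by diagnosis (`ad_slope_mean` vs `cn_slope_mean`); the rest
#' use `cn_slope_mean` for everyone. Ages are uniform on `age_range`, sex is
#' balanced Bernoulli, and diagnosis labels are assigned at random with
#' proportion `prop_ad`.
#'
#' @param scn a [psrrr_scenario()].
#' @return List with `values` (N x q_voxels x T array), `times`,
#'   `covariates` (tibble: sample_id, age, sex, diagnosis), and
#'   `true_slopes` (N x q_voxels matrix of noise-free slopes).
#' @export
simulate_longitudinal <- function(scn) {
  stopifnot(inherits(scn, "psrrr_scenario"))
  withr::with_seed(scn$seed + 4L, {
    n <- scn$n
    qv <- scn$q_voxels
    times <- scn$timepoints
    n_ad <- round(scn$prop_ad * n)
    diagnosis <- sample(c(rep("AD", n_ad), rep("CN", n - n_ad)))
    age <- runif(n, scn$age_range[1], scn$age_range[2])
    sex <- rbinom(n, 1, 0.5)
    slope_mean <- matrix(scn$cn_slope_mean, n, qv)
    if (scn$n_discriminative > 0) {
      disc <- seq_len(min(scn$n_discriminative, qv))
      slope_mean[diagnosis == "AD", disc] <- scn$ad_slope_mean
    }
    slopes <- slope_mean + matrix(rnorm(n * qv, sd = scn$slope_sd), n, qv)
    intercepts <- matrix(rnorm(n * qv, sd = scn$slope_sd), n, qv)
    values <- array(0, dim = c(n, qv, length(times)))
    for (t in seq_along(times)) {
      values[, , t] <- intercepts + slopes * times[t] +
        matrix(rnorm(n * qv, sd = scn$long_noise_sd), n, qv)
    }
    list(
      values = values, times = times,
      covariates = tibble::tibble(
        sample_id = sprintf("subj%04d", seq_len(n)),
        age = age, sex = sex, diagnosis = diagnosis
      ),
      true_slopes = slopes
    )
  })
}

#' Write a complete synthetic dataset in the pipeline's input formats
#'
#' Materialises one scenario as the on-disk formats the analysis reads: a
#' PLINK bed/bim/fam triple, a gene-location TSV, a GMT pathway file, a
#' covariate TSV, a phenotype TSV (`Y`), truth tables, and the scenario
#' parameters as a key=value file. Doubles as the fixture generator for
#' input/output tests.
#'
#' @param scn a [psrrr_scenario()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_scenario_files <- function(scn, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- simulate_genotypes(scn)
  pw <- simulate_pathways(scn, g)
  X <- standardise_design(g)
  ph <- simulate_phenotype(scn, X, pw$mapping)
  lg <- simulate_longitudinal(scn)
  paths <- list(
    plink = file.path(dir, "genotypes"),
    genes = file.path(dir, "genes.tsv"),
    gmt = file.path(dir, "pathways.gmt"),
    covariates = file.path(dir, "covariates.tsv"),
    phenotype = file.path(dir, "phenotype.tsv"),
    truth_snps = file.path(dir, "truth_causal_snps.tsv"),
    truth_pathways = file.path(dir, "truth_causal_pathways.tsv"),
    scenario = file.path(dir, "scenario.cfg")
  )
  write_plink(g, paths$plink)
  write_table(pw$genes, paths$genes)
  writeLines(
    vapply(names(pw$pathway_db), function(nm) {
      paste(c(nm, "synthetic", pw$pathway_db[[nm]]), collapse = "\t")
    }, character(1)),
    paths$gmt
  )
  write_table(lg$covariates, paths$covariates)
  ymat <- tibble::as_tibble(as.data.frame(ph$Y))
  names(ymat) <- sprintf("voxel%03d", seq_len(ncol(ph$Y)))
  readr::write_tsv(dplyr::bind_cols(
    tibble::tibble(sample_id = g$sample_ids), ymat
  ), paths$phenotype)
  write_table(tibble::tibble(
    snp_id = g$snps$snp_id[ph$truth$causal_snps],
    effect = ph$truth$b_star[ph$truth$causal_snps]
  ), paths$truth_snps)
  write_table(tibble::tibble(pathway = ph$truth$causal_pathways),
              paths$truth_pathways)
  writeLines(scenario_to_config(scn), paths$scenario)
  invisible(paths)
}

scenario_to_config <- function(scn) {
  vapply(names(scn), function(nm) {
    paste0(nm, " = ", paste(format(scn[[nm]], scientific = FALSE),
                            collapse = ","))
  }, character(1))
}

#' Rebuild a scenario from its key=value serialisation
#'
#' @param path a file written by [write_scenario_files()] (`scenario.cfg`).
#' @return A [psrrr_scenario()].
#' @export
read_scenario <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  args <- lapply(kv, function(x) {
    vals <- strsplit(x[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(vals))
    if (anyNA(num)) vals else num
  })
  names(args) <- vapply(kv, `[[`, character(1), 1)
  do.call(psrrr_scenario, args)
}
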