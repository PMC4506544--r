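#' Default gene panel
#'
#' The 87-assay qPCR panel used throughout the workflow. Genes are grouped
#' into four trajectory archetype clusters plus an "unclassified" remainder:
#'
#' * cluster 1 — gamete-inherited transcripts degraded during cleavage
#'   (present in the zygote, at least twofold down by 56 h);
#' * cluster 2 — stable transcripts (change of less than one unit);
#' * cluster 3 — embryonic-genome-activated transcripts absent from the
#'   zygote;
#' * cluster 4 — transcripts both inherited and re-activated;
#' * unclassified — flat profiles with no significant trajectory.
#'
#' Named members (AURKA, ZSCAN4, GAPDH, ...) are genes with well-described
#' behaviour in cleavage-stage embryos; the remainder of the panel carries
#' generic identifiers. Twelve genes form the default ploidy signature:
#' BUB1, CASP2, GAPDH and GADD45A are up-regulated in aneuploid blastomeres
#' and BUB3, CDK7, CTNNB1, E2F1, PTTG1, TP53, TSC2 and YBX2 down-regulated,
#' all within the first 30 h post pronuclear disappearance.
#'
#' @param n_genes Panel size. The default 87 reproduces the standard panel;
#'   other sizes rescale the cluster blocks proportionally.
#' @param cluster_proportions Fractions of the panel assigned to clusters
#'   1-4 (the remainder is unclassified).
#' @return A data.frame with columns `gene`, `cluster`
#'   (`"1"`,`"2"`,`"3"`,`"4"`,`"unclassified"`), `signature` (logical) and
#'   `direction` (+1 up in aneuploid, -1 down, 0 for non-signature genes).
#' @export
default_gene_table <- function(n_genes = 87,
                               cluster_proportions = c(29, 4, 10, 12) / 87) {
  stopifnot(n_genes >= 1, length(cluster_proportions) == 4,
            all(cluster_proportions >= 0), sum(cluster_proportions) <= 1)
  sizes <- floor(cluster_proportions * n_genes)
  if (sum(sizes) > n_genes) sizes <- pmax(sizes - 1L, 0L)

  named <- list(
    `1` = c("AURKA", "BUB3", "CDH1", "CDK7", "CRY1", "CTNNB1", "DNMT1",
            "DNMT3B", "DPPA3", "E2F1", "OOEP", "PADI6", "PDCD5", "PTTG1",
            "TP53", "TSC2", "YBX2"),
    `2` = c("AKT1", "BRCA1", "GAPDH", "NLRP5"),
    `3` = c("BUB1", "CASP2", "DDX20", "FASLG", "GADD45A", "SOX2", "ZSCAN4"),
    `4` = c("CCNA1", "CCND1", "MCL1", "ZAR1")
  )
  gene <- character(0)
  cluster <- character(0)
  extra <- 0L
  for (k in 1:4) {
    nm <- named[[as.character(k)]]
    nk <- sizes[k]
    ids <- nm[seq_len(min(nk, length(nm)))]
    while (length(ids) < nk) {
      extra <- extra + 1L
      ids <- c(ids, sprintf("GENE%03d", extra))
    }
    gene <- c(gene, ids)
    cluster <- c(cluster, rep(as.character(k), nk))
  }
  n_rest <- n_genes - length(gene)
  if (n_rest > 0) {
    ids <- sprintf("GENE%03d", extra + seq_len(n_rest))
    gene <- c(gene, ids)
    cluster <- c(cluster, rep("unclassified", n_rest))
  }
  sig_up <- c("BUB1", "CASP2", "GAPDH", "GADD45A")
  sig_dn <- c("BUB3", "CDK7", "CTNNB1", "E2F1", "PTTG1", "TP53", "TSC2",
              "YBX2")
  direction <- ifelse(gene %in% sig_up, 1L, ifelse(gene %in% sig_dn, -1L, 0L))
  data.frame(gene = gene, cluster = cluster,
             signature = direction != 0L, direction = direction,
             stringsAsFactors = FALSE)
}

#' Draw quadratic trajectory archetypes for a gene panel
#'
#' Each gene receives coefficients (a, b, c) of E(t) = a t^2 + b t + c on
#' the expression scale (units of qPCR cycles below the detection baseline,
#' a log2-like scale), with t in hours post pronuclear disappearance (PNd).
#' Endpoint values E0 = E(0) and E_final = E(56) are drawn inside bands
#' that respect the gene's cluster membership rule with a margin of at
#' least 0.4 units from every decision boundary, so the implied cluster and
#' origin labels are unambiguous ground truth:
#'
#' * cluster 1: E0 in (3, 9), E_final in (0.2, 1.6), mild convexity;
#' * cluster 2: E0 in (3, 7), |E_final - E0| < 0.5;
#' * cluster 3: E0 in (0.2, 1.4), E_final in (2.8, 9), a > 0 so an
#'   activation time exists;
#' * cluster 4: E0 in (2.5, 5), E_final = E0 + (1.4, 4), a > 0;
#' * unclassified: constant E(t) = c with c in (3, 6).
#'
#' Origin labels follow the presence rule (value above 2 at an endpoint
#' means the transcript is present there): gametic, EGA, both or neither.
#'
#' @param gene_table As from [default_gene_table()]; RNG state is consumed.
#' @param t_final Final time point in hours (default 56).
#' @return `gene_table` with columns `a`, `b`, `c`, `E0`, `E_final`,
#'   `origin` appended.
#' @export
draw_archetypes <- function(gene_table, t_final = 56) {
  n <- nrow(gene_table)
  a <- b <- cc <- E0 <- Ef <- numeric(n)
  for (i in seq_len(n)) {
    cl <- gene_table$cluster[i]
    if (cl == "1") {
      E0[i] <- stats::runif(1, 3, 9)
      Ef[i] <- stats::runif(1, 0.2, 1.6)
      a[i] <- stats::runif(1, 0.0001, 0.0008)
    } else if (cl == "2") {
      E0[i] <- stats::runif(1, 3, 7)
      Ef[i] <- E0[i] + stats::runif(1, -0.5, 0.5)
      a[i] <- stats::runif(1, -0.0003, 0.0003)
    } else if (cl == "3") {
      E0[i] <- stats::runif(1, 0.2, 1.4)
      Ef[i] <- stats::runif(1, 2.8, 9)
      a[i] <- stats::runif(1, 0.0006, 0.002)
    } else if (cl == "4") {
      E0[i] <- stats::runif(1, 2.5, 5)
      Ef[i] <- E0[i] + stats::runif(1, 1.4, 4)
      a[i] <- stats::runif(1, 0.0006, 0.002)
    } else {
      E0[i] <- stats::runif(1, 3, 6)
      Ef[i] <- E0[i]
      a[i] <- 0
    }
    cc[i] <- E0[i]
    b[i] <- (Ef[i] - E0[i]) / t_final - t_final * a[i]
  }
  gene_table$a <- a
  gene_table$b <- b
  gene_table$c <- cc
  gene_table$E0 <- E0
  gene_table$E_final <- Ef
  gene_table$origin <- classify_origin(E0, Ef)
  gene_table
}

#' Evaluate archetype trajectories
#'
#' @param gene_table Archetype table from [draw_archetypes()].
#' @param time Vector of times (hours post PNd).
#' @return Matrix of noise-free expression values, genes x times.
#' @export
archetype_expression <- function(gene_table, time) {
  outer(seq_len(nrow(gene_table)), time, function(i, t)
    gene_table$a[i] * t^2 + gene_table$b[i] * t + gene_table$c[i])
}
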