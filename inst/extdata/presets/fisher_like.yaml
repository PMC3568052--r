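# Fisher-like dataset preset: five genetic clusters.
# Emulates the sampling design of a 34-site mustelid microsatellite study
# (772 individuals, 7-48 per site, 16 loci, K = 5 clusters of 6-7 sites) with
# mean pairwise Weir-Cockerham theta calibrated to 0.068 and clearly larger
# between-cluster than within-cluster differentiation.
n_sites: 34
n_loci: 16
n_alleles: 8
K: 5
sizes:
  mean: 21.2
  sd: 7.1
  min: 7
  max: 48
theta_cluster: 18
theta_site: 60
ibd_decay: 0.5
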