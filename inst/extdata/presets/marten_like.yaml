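# Marten-like dataset preset: one genetic cluster, weak structure.
# Emulates the sampling design of a 29-site boreal mustelid microsatellite
# study (653 individuals, 11-47 per site, 12 loci) with mean pairwise
# Weir-Cockerham theta calibrated to 0.022.
n_sites: 29
n_loci: 12
n_alleles: 8
K: 1
sizes:
  mean: 22.5
  sd: 5.9
  min: 11
  max: 47
theta_cluster: 50
theta_site: 60
ibd_decay: 0.5
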