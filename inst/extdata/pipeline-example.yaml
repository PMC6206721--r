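# Example end-to-end panel comparison at desk scale.
# Run with: runPipeline("pipeline-example.yaml", outDir = "out")
version: 1
seed: 5
input:
  type: simulate        # or: type: vcf, vcf: path.vcf, labels: labels.tsv
  nPerPop: 10
  mSnps: 4000
panels:
  - name: reference
    scheme: all
  - name: beadchip_like
    scheme: aim
    nSites: 400
    fractionAims: 0.8
    mode: delta_pair
    pair: [SP1a, SP2a]
  - name: random
    scheme: random
    nSites: 400
reference: reference
qc:
  minCarriers: 2
pruning:
  enabled: false
pca:
  components: 5
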