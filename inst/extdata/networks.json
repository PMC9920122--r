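{
  "networks": {
    "FPN": {
      "rois": [
        "Superior frontal gyrus, dorsolateral-L",
        "Superior frontal gyrus, dorsolateral-R",
        "Superior frontal gyrus, orbital part-L",
        "Superior frontal gyrus, orbital part-R",
        "Middle frontal gyrus-L",
        "Middle frontal gyrus-R",
        "Middle frontal gyrus, orbital part-L",
        "Middle frontal gyrus, orbital part-R",
        "Inferior frontal gyrus, triangular part-L",
        "Inferior frontal gyrus, triangular part-R",
        "Inferior parietal, but supramarginal and angular gyri-L",
        "Inferior parietal, but supramarginal and angular gyri-R"
      ],
      "reduce": false
    },
    "SAN": {
      "rois": [
        "Middle frontal gyrus-L",
        "Middle frontal gyrus-R",
        "Inferior frontal gyrus, triangular part-L",
        "Inferior frontal gyrus, triangular part-R",
        "Insula-L",
        "Insula-R",
        "Anterior cingulate and paracingulate gyri-L",
        "Anterior cingulate and paracingulate gyri-R",
        "Median cingulate and paracingulate gyri-L",
        "Median cingulate and paracingulate gyri-R",
        "Superior parietal gyrus-L",
        "Superior parietal gyrus-R"
      ],
      "reduce": false
    },
    "ATN": {
      "rois": [
        "Middle frontal gyrus-L",
        "Middle frontal gyrus-R",
        "Inferior frontal gyrus, triangular part-L",
        "Inferior frontal gyrus, triangular part-R",
        "Superior parietal gyrus-L",
        "Superior parietal gyrus-R",
        "Inferior parietal, but supramarginal and angular gyri-L",
        "Inferior parietal, but supramarginal and angular gyri-R",
        "Superior temporal gyrus-L",
        "Superior temporal gyrus-R"
      ],
      "reduce": false
    }
  }
}
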