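{
  "name": "navy-food-standard (reconstructed, synthetic)",
  "provenance": "standard",
  "energy_kcal": 4532,
  "protein_g": 164.6,
  "fat_g": 145.3,
  "carb_g": null,
  "note": "Composition reconstructed by arithmetic from reported ration-vs-standard differences, not copied from a published table; an alternative stated energy value of 4520 kcal exists but is inconsistent with those differences. Carbohydrate content is not reconstructible. User-supplied standards override this fixture."
}
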