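{
  "schema_version": 1,
  "crowding_budget": 1,
  "biomass_id": "BIOMASS",
  "substrate_exchange_ids": [
    ["EX_glc"],
    ["EX_gal"],
    ["EX_mal"],
    ["EX_lac"],
    ["EX_gly"]
  ],
  "acetate_exchange_id": "EX_ac",
  "metabolites": [
    {
      "id": "glc_e",
      "name": "glucose (medium)",
      "carbon_atoms": 6,
      "is_external": true
    },
    {
      "id": "gal_e",
      "name": "galactose (medium)",
      "carbon_atoms": 6,
      "is_external": true
    },
    {
      "id": "mal_e",
      "name": "maltose (medium)",
      "carbon_atoms": 12,
      "is_external": true
    },
    {
      "id": "lac_e",
      "name": "lactate (medium)",
      "carbon_atoms": 3,
      "is_external": true
    },
    {
      "id": "gly_e",
      "name": "glycerol (medium)",
      "carbon_atoms": 3,
      "is_external": true
    },
    {
      "id": "glc_c",
      "name": "glucose",
      "carbon_atoms": 6,
      "is_external": false
    },
    {
      "id": "gal_c",
      "name": "galactose",
      "carbon_atoms": 6,
      "is_external": false
    },
    {
      "id": "mal_c",
      "name": "maltose",
      "carbon_atoms": 12,
      "is_external": false
    },
    {
      "id": "lac_c",
      "name": "lactate",
      "carbon_atoms": 3,
      "is_external": false
    },
    {
      "id": "gly_c",
      "name": "glycerol",
      "carbon_atoms": 3,
      "is_external": false
    },
    {
      "id": "pyr",
      "name": "pyruvate pool",
      "carbon_atoms": 3,
      "is_external": false
    },
    {
      "id": "ac_c",
      "name": "acetate",
      "carbon_atoms": 2,
      "is_external": false
    },
    {
      "id": "ac_e",
      "name": "acetate (medium)",
      "carbon_atoms": 2,
      "is_external": true
    },
    {
      "id": "bmC",
      "name": "biomass carbon",
      "carbon_atoms": 1,
      "is_external": false
    }
  ],
  "reactions": [
    {
      "id": "EX_glc",
      "kind": "exchange",
      "lower_bound": 0,
      "upper_bound": 10,
      "crowding_coefficient": 0,
      "stoichiometry": {
        "glc_c": 1,
        "glc_e": -1
      }
    },
    {
      "id": "EX_gal",
      "kind": "exchange",
      "lower_bound": 0,
      "upper_bound": 8,
      "crowding_coefficient": 0,
      "stoichiometry": {
        "gal_c": 1,
        "gal_e": -1
      }
    },
    {
      "id": "EX_mal",
      "kind": "exchange",
      "lower_bound": 0,
      "upper_bound": 4,
      "crowding_coefficient": 0,
      "stoichiometry": {
        "mal_c": 1,
        "mal_e": -1
      }
    },
    {
      "id": "EX_lac",
      "kind": "exchange",
      "lower_bound": 0,
      "upper_bound": 15,
      "crowding_coefficient": 0,
      "stoichiometry": {
        "lac_c": 1,
        "lac_e": -1
      }
    },
    {
      "id": "EX_gly",
      "kind": "exchange",
      "lower_bound": 0,
      "upper_bound": 15,
      "crowding_coefficient": 0,
      "stoichiometry": {
        "gly_c": 1,
        "gly_e": -1
      }
    },
    {
      "id": "CAT_glc",
      "kind": "internal",
      "lower_bound": 0,
      "upper_bound": null,
      "crowding_coefficient": 0.015,
      "stoichiometry": {
        "glc_c": -1,
        "pyr": 2
      }
    },
    {
      "id": "CAT_gal",
      "kind": "internal",
      "lower_bound": 0,
      "upper_bound": null,
      "crowding_coefficient": 0.045,
      "stoichiometry": {
        "gal_c": -1,
        "pyr": 2
      }
    },
    {
      "id": "CAT_mal",
      "kind": "internal",
      "lower_bound": 0,
      "upper_bound": null,
      "crowding_coefficient": 0.06,
      "stoichiometry": {
        "mal_c": -1,
        "pyr": 4
      }
    },
    {
      "id": "CAT_lac",
      "kind": "internal",
      "lower_bound": 0,
      "upper_bound": null,
      "crowding_coefficient": 0.0375,
      "stoichiometry": {
        "lac_c": -1,
        "pyr": 1
      }
    },
    {
      "id": "CAT_gly",
      "kind": "internal",
      "lower_bound": 0,
      "upper_bound": null,
      "crowding_coefficient": 0.06,
      "stoichiometry": {
        "gly_c": -1,
        "pyr": 1
      }
    },
    {
      "id": "OXPHOS",
      "kind": "internal",
      "lower_bound": 0,
      "upper_bound": null,
      "crowding_coefficient": 0.12,
      "stoichiometry": {
        "bmC": 3,
        "pyr": -1
      }
    },
    {
      "id": "FERM",
      "kind": "internal",
      "lower_bound": 0,
      "upper_bound": null,
      "crowding_coefficient": 0.0225,
      "stoichiometry": {
        "ac_c": 1,
        "bmC": 1,
        "pyr": -1
      }
    },
    {
      "id": "ACUSE",
      "kind": "internal",
      "lower_bound": 0,
      "upper_bound": null,
      "crowding_coefficient": 0.15,
      "stoichiometry": {
        "ac_c": -1,
        "bmC": 2
      }
    },
    {
      "id": "EX_ac",
      "kind": "exchange",
      "lower_bound": -10,
      "upper_bound": null,
      "crowding_coefficient": 0,
      "stoichiometry": {
        "ac_c": -1,
        "ac_e": 1
      }
    },
    {
      "id": "BIOMASS",
      "kind": "biomass",
      "lower_bound": 0,
      "upper_bound": null,
      "crowding_coefficient": 0.015,
      "stoichiometry": {
        "bmC": -40
      }
    }
  ]
}
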