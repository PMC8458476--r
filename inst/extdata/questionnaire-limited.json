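{
  "version": "1.0",
  "start_id": "lh_adopted",
  "languages": [
    "en",
    "es"
  ],
  "questions": [
    {
      "id": "lh_adopted",
      "module": "limited",
      "kind": "yes_no",
      "text_key": "q.lh_adopted",
      "rules": [
        {
          "goto": "lh_know_mat"
        }
      ]
    },
    {
      "id": "lh_know_mat",
      "module": "limited",
      "kind": "yes_no",
      "text_key": "q.lh_know_mat",
      "rules": [
        {
          "goto": "lh_know_pat"
        }
      ]
    },
    {
      "id": "lh_know_pat",
      "module": "limited",
      "kind": "yes_no",
      "text_key": "q.lh_know_pat",
      "rules": [
        {
          "goto": "lh_fem45_mat"
        }
      ]
    },
    {
      "id": "lh_fem45_mat",
      "module": "limited",
      "kind": "count",
      "text_key": "q.lh_fem45_mat",
      "rules": [
        {
          "goto": "lh_fem45_pat"
        }
      ]
    },
    {
      "id": "lh_fem45_pat",
      "module": "limited",
      "kind": "count",
      "text_key": "q.lh_fem45_pat",
      "rules": [
        {
          "goto": "lh_prior_ls"
        }
      ]
    },
    {
      "id": "lh_prior_ls",
      "module": "limited",
      "kind": "yes_no",
      "text_key": "q.lh_prior_ls",
      "rules": [
        {
          "goto": "lh_prior_hboc"
        }
      ]
    },
    {
      "id": "lh_prior_hboc",
      "module": "limited",
      "kind": "yes_no",
      "text_key": "q.lh_prior_hboc",
      "rules": [
        {
          "goto": "TERMINAL"
        }
      ]
    }
  ]
}
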