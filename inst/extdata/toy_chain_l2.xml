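<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">
  <model id="toy_chain_l2" name="Linear chain toy model (COBRA-style Level 2)">
    <listOfCompartments>
      <compartment id="c" name="cytosol"/>
      <compartment id="e" name="extracellular"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_A_c" name="A" compartment="c"/>
      <species id="M_B_c" name="B" compartment="c"/>
      <species id="M_B_e" name="B external" compartment="e" boundaryCondition="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R_U" name="A uptake" reversible="false">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>GENE_ASSOCIATION: g1 and (g2 or g3)</p>
          </body>
        </notes>
        <listOfProducts>
          <speciesReference species="M_A_c" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R_R" name="A to B" reversible="false">
        <listOfReactants>
          <speciesReference species="M_A_c"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_B_c"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R_T" name="B export transport" reversible="true">
        <listOfReactants>
          <speciesReference species="M_B_c"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_B_e"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="-1000"/>
            <parameter id="UPPER_BOUND" value="1000"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R_EX_B" name="B drain" reversible="false">
        <listOfReactants>
          <speciesReference species="M_B_e"/>
        </listOfReactants>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
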